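# Benchmark orchestrator: the full trait x canopy-stage x environment-set
# x method comparison in one call, Table-shaped long output plus a
# reproducibility manifest.

#' Which trait/stage/environment combinations are measurable
#'
#' The study design determines what exists: LAI only under FI at anthesis,
#' Delta13C only at maturity, chlorophyll at anthesis and grain filling,
#' carbohydrates at anthesis and maturity, the yield components at
#' maturity. Encoded as data so the orchestrator can validate requests.
#'
#' @return Tibble `trait`, `measurement_stage`, `environments` (comma
#'   string of valid environment sets).
#' @export
trait_validity <- function() {
  all3 <- "FI,WS,WS+FI"
  dplyr::bind_rows(
    tibble(trait = c("SM2", "KPS", "TKW", "GY", "D13C"),
           measurement_stage = "m", environments = all3),
    tibble(trait = c("Chl", "WSC", "WSCC"), measurement_stage = "an",
           environments = all3),
    tibble(trait = "Chl", measurement_stage = "gf", environments = all3),
    tibble(trait = c("WSC", "WSCC"), measurement_stage = "m",
           environments = all3),
    tibble(trait = "LAI", measurement_stage = "an", environments = "FI"))
}

# Deterministic per-cell seed derived from the master seed and the cell
# coordinates, so adding a method or trait never shifts other cells' folds.
cell_seed <- function(master_seed, ...) {
  h <- as.double(master_seed) %% 2147483647
  for (part in unlist(list(...))) {
    for (b in utf8ToInt(as.character(part))) {
      h <- (h * 31 + b) %% 2147483647
    }
  }
  as.integer(h)
}

benchmark_methods <- function() {
  list(regression = c("pcr", "plsr", "rr", "svr"),
       classification = c("pca_lda", "plsda", "knn"),
       screening = "sri")
}

run_regression_cell <- function(x, y, method, seed) {
  fit <- switch(method,
                pcr = fit_pcr(x, y, seed = seed),
                plsr = fit_plsr(x, y, seed = seed),
                rr = fit_ridge(x, y, seed = seed),
                svr = fit_svr(x, y, seed = seed))
  g <- glance(fit)
  tidyr::pivot_longer(
    g[c("r2_cal", "rmse_cal", "ia_cal", "r2_val", "rmse_val", "ia_val")],
    dplyr::everything(), names_to = c("metric", "split"), names_sep = "_",
    values_to = "value") |>
    dplyr::mutate(detail = g$selected, n = g$n)
}

run_classification_cell <- function(x, y, method, fraction, seed) {
  lab <- dichotomize(y, fraction = fraction)
  fit <- switch(method,
                pca_lda = fit_pca_lda(x, lab, seed = seed),
                plsda = fit_plsda(x, lab, seed = seed),
                knn = fit_knn(x, lab, seed = seed))
  g <- glance(fit)
  keep <- c("accuracy_cal", "error_rate_cal", "prediction_rate_class1_cal",
            "prediction_rate_class2_cal", "accuracy_val", "error_rate_val",
            "prediction_rate_class1_val", "prediction_rate_class2_val")
  long <- tidyr::pivot_longer(g[keep], dplyr::everything(),
                              names_to = "name", values_to = "value")
  dplyr::mutate(long,
                split = sub(".*_(cal|val)$", "\\1", .data$name),
                metric = sub("_(cal|val)$", "", .data$name),
                detail = sprintf("%s; threshold=%.4g", g$selected,
                                 lab$threshold),
                n = g$n) |>
    dplyr::select(dplyr::all_of(c("metric", "split", "value", "detail", "n")))
}

run_sri_cell <- function(spectra_cell, y, registry) {
  idx <- compute_indices(spectra_cell, registry)
  scr <- screen_indices(idx, y)
  best <- scr[1L, ]
  tibble(metric = c("r2", "rmse"), split = "cal",
         value = c(best$r2, best$rmse),
         detail = paste0("best_sri=", best$index), n = best$n)
}

#' Run the full benchmark comparison
#'
#' For every requested trait (at its measurement stage), canopy stage,
#' environment set and method, aligns spectra with the trait, preprocesses
#' (missing-value exclusion, optional LOF screening, z-score normalization
#' for regressors / mean-centring for classifiers), runs the method and
#' collects metrics into one long tibble. A failing cell is recorded with
#' `status = "failed"` and never interrupts the other cells. Per-cell
#' seeds derive deterministically from `seed` and the cell coordinates, so
#' two runs with the same master seed are identical and adding a method
#' does not shift the folds of the others.
#'
#' @param spectra Spectra tibble (e.g. from [generate_spectra()] or
#'   [read_spectra()]); noise regions are trimmed with `noise_regions`
#'   before modelling.
#' @param traits Long trait tibble.
#' @param traits_stages Tibble with columns `trait`, `measurement_stage`
#'   selecting what to predict; defaults to every valid combination
#'   present in `traits`.
#' @param stages Canopy stages to use (`"AN"`, `"GF"`).
#' @param environments Environment sets (`"WS"`, `"FI"`, `"WS+FI"`).
#' @param methods Any of `"sri"`, `"pcr"`, `"plsr"`, `"rr"`, `"svr"`,
#'   `"pca_lda"`, `"plsda"`, `"knn"`.
#' @param fraction Elite dichotomization fraction (default 0.8).
#' @param lof_k LOF neighbourhood size; 0 disables outlier screening.
#' @param noise_regions Wavelength regions to trim; `NULL` keeps all bands.
#' @param registry Index registry for `"sri"` screening.
#' @param seed Master seed.
#' @return A `benchmark_result` tibble: one row per (trait, stage,
#'   environment set, method, metric, split), with a `manifest` attribute
#'   recording seeds, sizes and preprocessing counts per cell.
#' @export
run_benchmark <- function(spectra, traits,
                          traits_stages = NULL,
                          stages = c("AN", "GF"),
                          environments = c("WS", "FI", "WS+FI"),
                          methods = c("sri", "rr", "plsda"),
                          fraction = 0.8, lof_k = 20,
                          noise_regions = default_noise_regions(),
                          registry = sri_registry(), seed = 1) {
  if (length(methods) == 0L) {
    abort("no methods requested", class = "spectrait_config_error")
  }
  mm <- benchmark_methods()
  unknown <- setdiff(methods, unlist(mm))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown method(s): %s", paste(unknown, collapse = ", ")),
          class = "spectrait_config_error")
  }
  traits <- as_tibble(traits)
  validity <- trait_validity()
  if (is.null(traits_stages)) {
    traits_stages <- dplyr::semi_join(
      unique(traits[c("trait", "measurement_stage")]),
      validity, by = c("trait", "measurement_stage"))
  }
  if (nrow(traits_stages) == 0L) {
    abort("no traits requested", class = "spectrait_config_error")
  }
  if (!is.null(noise_regions)) {
    spectra <- trim_noise_bands(spectra, noise_regions)
  }
  results <- list()
  cells <- list()
  for (ti in seq_len(nrow(traits_stages))) {
    tr <- traits_stages$trait[ti]; ms <- traits_stages$measurement_stage[ti]
    vrow <- validity[validity$trait == tr & validity$measurement_stage == ms, ]
    valid_envs <- if (nrow(vrow) == 1L)
      strsplit(vrow$environments, ",")[[1L]] else environments
    for (st in stages) for (env in intersect(environments, valid_envs)) {
      aligned <- align_observations(spectra, traits, tr, ms,
                                    stage = st, environment = env)
      bands <- band_cols(aligned)
      for (method in methods) {
        sd_cell <- cell_seed(seed, tr, ms, st, env, method)
        coords <- tibble(trait = tr, measurement_stage = ms,
                         spectra_stage = st, environment = env,
                         method = method, seed = sd_cell)
        res <- tryCatch({
          kind <- if (method %in% mm$regression) "regression"
                  else if (method %in% mm$classification) "classification"
                  else "screening"
          mode <- if (kind == "classification") "mean_center" else "zscore"
          pp <- preprocess(aligned[bands], aligned$trait_value,
                           mode = if (kind == "screening") "none" else mode,
                           lof_k = lof_k)
          cell <- if (kind == "regression") {
            run_regression_cell(pp$x, pp$y, method, sd_cell)
          } else if (kind == "classification") {
            run_classification_cell(pp$x, pp$y, method, fraction, sd_cell)
          } else {
            ok_rows <- which(!is.na(aligned$trait_value))
            run_sri_cell(aligned[ok_rows, c("observation_id", bands)],
                         aligned$trait_value[ok_rows], registry)
          }
          cells[[length(cells) + 1L]] <- dplyr::mutate(
            coords, n_input = pp$report$n_input,
            n_missing_dropped = pp$report$n_missing_dropped,
            n_outliers_dropped = pp$report$n_outliers_dropped,
            status = "ok")
          dplyr::bind_cols(coords[rep(1L, nrow(cell)), ], cell,
                           tibble(status = rep("ok", nrow(cell))))
        }, error = function(e) {
          cells[[length(cells) + 1L]] <<- dplyr::mutate(
            coords, n_input = NA_integer_, n_missing_dropped = NA_integer_,
            n_outliers_dropped = NA_integer_, status = "failed")
          dplyr::bind_cols(coords,
                           tibble(metric = NA_character_, split = NA_character_,
                                  value = NA_real_,
                                  detail = conditionMessage(e),
                                  n = NA_integer_, status = "failed"))
        })
        results[[length(results) + 1L]] <- res
      }
    }
  }
  out <- dplyr::bind_rows(results)
  attr(out, "manifest") <- list(
    master_seed = seed,
    package_version = as.character(utils::packageVersion("spectrait")),
    fraction = fraction, lof_k = lof_k,
    noise_regions = noise_regions,
    methods = methods, stages = stages, environments = environments,
    cells = dplyr::bind_rows(cells))
  class(out) <- unique(c("benchmark_result", class(out)))
  out
}

#' Write benchmark results and manifest to a directory
#'
#' @param result A `benchmark_result` from [run_benchmark()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `results.csv` (long table) and
#'   `manifest.json`.
#' @export
write_benchmark <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(as_tibble(result), file.path(dir, "results.csv"))
  man <- attr(result, "manifest")
  man$cells <- as.data.frame(man$cells)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
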