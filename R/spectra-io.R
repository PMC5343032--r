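#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

#' Identify band (wavelength) columns of a spectra table
#'
#' Spectra tables are wide tibbles: metadata columns (at least
#' `observation_id`) followed by one column per wavelength, named by its
#' integer nanometre value (`"350"`, `"351"`, ...).
#'
#' @param spectra A spectra tibble.
#' @return `band_cols()`: character vector of band column names;
#'   `wavelengths()`: the corresponding integer nanometre grid.
#' @export
#' @examples
#' s <- tibble::tibble(observation_id = "p1", `350` = 0.1, `351` = 0.2)
#' band_cols(s)
#' wavelengths(s)
band_cols <- function(spectra) {
  nm <- names(spectra)
  nm[grepl("^[0-9]+$", nm)]
}

#' @rdname band_cols
#' @export
wavelengths <- function(spectra) {
  as.integer(band_cols(spectra))
}

meta_cols <- function(spectra) {
  setdiff(names(spectra), band_cols(spectra))
}

new_spectra <- function(df) {
  class(df) <- unique(c("spectra_tbl", class(as_tibble(df))))
  df
}

#' Validate a canopy reflectance spectra table
#'
#' Checks the contract every downstream step relies on: an `observation_id`
#' column with unique values, a strictly increasing integer wavelength grid
#' within 350--2500 nm, and finite reflectance values in \[0, 1\]. Tables on
#' a percent scale (any value > 1.5) are rescaled to fractions with a
#' warning, mirroring the two conventions found in field spectroradiometer
#' exports.
#'
#' @param spectra Wide spectra table (data frame or tibble).
#' @param strict If `TRUE` (default) values outside \[0, 1\] after rescaling
#'   raise an error naming the offending cell; if `FALSE` they are replaced
#'   by `NA` with a warning.
#' @return The validated spectra tibble (classed `spectra_tbl`).
#' @export
validate_spectra <- function(spectra, strict = TRUE) {
  spectra <- as_tibble(spectra)
  if (!"observation_id" %in% names(spectra)) {
    abort("spectra table must contain an `observation_id` column",
          class = "spectrait_format_error")
  }
  bands <- band_cols(spectra)
  if (length(bands) == 0L) {
    abort("no wavelength columns found (integer-named columns such as `350`)",
          class = "spectrait_format_error")
  }
  wl <- as.integer(bands)
  if (any(wl < 350L) || any(wl > 2500L)) {
    abort("wavelength labels must lie within [350, 2500] nm",
          class = "spectrait_format_error")
  }
  if (any(diff(wl) <= 0L)) {
    abort("wavelength labels must be strictly increasing",
          class = "spectrait_format_error")
  }
  if (anyDuplicated(spectra$observation_id)) {
    abort("`observation_id` values must be unique within a spectra table",
          class = "spectrait_format_error")
  }
  x <- as.matrix(spectra[bands])
  if (!is.numeric(x)) {
    bad <- which(!vapply(spectra[bands], is.numeric, logical(1)))[1L]
    abort(sprintf("non-numeric reflectance column `%s`", bands[bad]),
          class = "spectrait_parse_error")
  }
  # Percent-scale exports: only rescale when the bulk of the table is on
  # that scale, so a lone out-of-range cell is still reported as an error.
  if (max(x, na.rm = TRUE) > 1.5 && stats::median(x, na.rm = TRUE) > 1.5 &&
      max(x, na.rm = TRUE) <= 150) {
    warn("reflectance appears to be on a percent scale; dividing by 100")
    x <- x / 100
  }
  bad <- which(!is.finite(x) & !is.na(x) | x < 0 | x > 1, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    msg <- sprintf(
      "reflectance out of [0, 1] at observation `%s`, band %s nm (value %g)",
      spectra$observation_id[i], bands[j], x[i, j])
    if (strict) abort(msg, class = "spectrait_validation_error")
    warn(paste0(msg, "; set to NA"))
    x[cbind(bad[, 1L], bad[, 2L])] <- NA_real_
  }
  spectra[bands] <- as_tibble(as.data.frame(x, check.names = FALSE))
  new_spectra(spectra)
}

#' Read and write canopy reflectance spectra
#'
#' Spectra files are delimited text with a header row of metadata names
#' followed by integer wavelength labels, e.g.
#' `observation_id,genotype_id,environment,stage,350,351,...,2500`.
#'
#' @param path File path (CSV by default).
#' @param delim Field delimiter, `","` by default.
#' @inheritParams validate_spectra
#' @return `read_spectra()` returns a validated spectra tibble;
#'   `write_spectra()` writes `spectra` to `path` and returns it invisibly.
#' @export
read_spectra <- function(path, delim = ",", strict = TRUE) {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  prob <- readr::problems(raw)
  if (nrow(prob) > 0L) {
    abort(sprintf("parse error in `%s`: row %d, column %d (%s)",
                  path, prob$row[1L], prob$col[1L], prob$expected[1L]),
          class = "spectrait_parse_error")
  }
  validate_spectra(raw, strict = strict)
}

#' @rdname read_spectra
#' @param spectra Spectra tibble to write.
#' @export
write_spectra <- function(spectra, path, delim = ",") {
  readr::write_delim(as_tibble(spectra), path, delim = delim)
  invisible(spectra)
}

#' Read and write trait tables
#'
#' Trait tables are long-format delimited text with columns
#' `observation_id,trait,measurement_stage,value`, one row per measured
#' trait per plot. Traits are tagged with the stage at which they were
#' measured: anthesis (`an`), grain filling (`gf`), or maturity (`m`).
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @return A validated trait tibble.
#' @export
read_traits <- function(path, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  validate_traits(raw)
}

#' @rdname read_traits
#' @param traits Trait tibble to write.
#' @export
write_traits <- function(traits, path, delim = ",") {
  readr::write_delim(as_tibble(traits), path, delim = delim)
  invisible(traits)
}

#' @rdname read_traits
#' @param traits Long-format trait table to validate.
#' @export
validate_traits <- function(traits) {
  traits <- as_tibble(traits)
  need <- c("observation_id", "trait", "measurement_stage", "value")
  miss <- setdiff(need, names(traits))
  if (length(miss) > 0L) {
    abort(sprintf("trait table is missing column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "spectrait_format_error")
  }
  key <- paste(traits$observation_id, traits$trait, traits$measurement_stage)
  if (anyDuplicated(key)) {
    abort("duplicate (observation_id, trait, measurement_stage) entries",
          class = "spectrait_format_error")
  }
  if (any(is.infinite(traits$value), na.rm = TRUE)) {
    abort("trait values must be finite (missing values should be absent rows or NA)",
          class = "spectrait_validation_error")
  }
  traits
}

#' Average repeated scans of the same plot
#'
#' Field protocols record several scans per plot (three in the motivating
#' study) and carry the per-wavelength arithmetic mean into analysis.
#' Metadata columns must be constant within a group and are retained.
#'
#' @param spectra Spectra tibble in which `group` identifies repeat scans of
#'   one plot.
#' @param group Name of the grouping column, `"observation_id"` by default.
#' @return Spectra tibble with one row per group.
#' @export
average_scans <- function(spectra, group = "observation_id") {
  spectra <- as_tibble(spectra)
  bands <- band_cols(spectra)
  metas <- setdiff(meta_cols(spectra), group)
  for (m in metas) {
    n_distinct <- vapply(split(spectra[[m]], spectra[[group]]),
                         function(v) length(unique(v)), integer(1))
    if (any(n_distinct > 1L)) {
      abort(sprintf("metadata column `%s` varies within a scan group", m),
            class = "spectrait_alignment_error")
    }
  }
  out <- spectra %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group, metas)))) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(bands), mean), .groups = "drop") %>%
    dplyr::select(dplyr::all_of(c(group, metas, bands)))
  new_spectra(out)
}

#' Default spectral noise-deletion regions
#'
#' Atmospheric water-vapour and detector-edge regions that are routinely
#' unusable in field spectra from ASD-class instruments: 350--399,
#' 1350--1480, 1800--1980 and 2401--2500 nm. Interval ends are inclusive.
#'
#' @return A list of `c(lo, hi)` integer pairs (nm).
#' @export
default_noise_regions <- function() {
  list(c(350L, 399L), c(1350L, 1480L), c(1800L, 1980L), c(2401L, 2500L))
}

#' Remove noisy wavelength regions from a spectra table
#'
#' Pure column selection: retained reflectance values are untouched, and
#' metadata columns are preserved. Interval ends are inclusive.
#'
#' @param spectra Spectra tibble.
#' @param regions List of `c(lo_nm, hi_nm)` pairs; defaults to
#'   [default_noise_regions()].
#' @return Spectra tibble restricted to the retained wavelength grid.
#' @export
trim_noise_bands <- function(spectra, regions = default_noise_regions()) {
  spectra <- as_tibble(spectra)
  wl <- wavelengths(spectra)
  drop <- rep(FALSE, length(wl))
  for (r in regions) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < 350 || r[2] > 2500) {
      abort("each region must be c(lo, hi) with 350 <= lo <= hi <= 2500",
            class = "spectrait_format_error")
    }
    drop <- drop | (wl >= r[1] & wl <= r[2])
  }
  if (all(drop)) {
    abort("noise regions remove every wavelength (degenerate spectrum)",
          class = "spectrait_degenerate_error")
  }
  keep_bands <- band_cols(spectra)[!drop]
  new_spectra(spectra[c(meta_cols(spectra), keep_bands)])
}

#' Align spectra with a trait across plot observations
#'
#' Joins one trait (at one measurement stage) onto spectra rows, optionally
#' restricted to one canopy assessment stage (`AN`/`GF`) and environment set
#' (`"FI"`, `"WS"`, or `"WS+FI"`). Spectra carry a `plot_id` when the same
#' plot was scanned at several stages; the join then uses `plot_id`,
#' otherwise `observation_id`.
#'
#' @param spectra Spectra tibble.
#' @param traits Long-format trait tibble.
#' @param trait Trait name (e.g. `"GY"`).
#' @param measurement_stage Trait measurement stage: `"an"`, `"gf"` or `"m"`.
#' @param stage Optional canopy stage filter (`"AN"` or `"GF"`).
#' @param environment Optional environment set (`"FI"`, `"WS"`, `"WS+FI"`).
#' @return The filtered spectra tibble with a `trait_value` column appended;
#'   rows with no trait record get `NA`.
#' @export
align_observations <- function(spectra, traits, trait, measurement_stage,
                               stage = NULL, environment = NULL) {
  spectra <- as_tibble(spectra)
  if (!is.null(stage) && "stage" %in% names(spectra)) {
    spectra <- dplyr::filter(spectra, .data$stage %in% !!stage)
  }
  if (!is.null(environment) && "environment" %in% names(spectra)) {
    envs <- if (identical(environment, "WS+FI")) c("WS", "FI") else environment
    spectra <- dplyr::filter(spectra, .data$environment %in% envs)
  }
  tt <- dplyr::filter(as_tibble(traits),
                      .data$trait == !!trait,
                      .data$measurement_stage == !!measurement_stage)
  key <- if ("plot_id" %in% names(spectra)) "plot_id" else "observation_id"
  tt <- dplyr::select(tt, dplyr::all_of("observation_id"), trait_value = "value")
  names(tt)[1L] <- key
  out <- dplyr::left_join(spectra, tt, by = key)
  new_spectra(out)
}
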