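# Synthetic study generator: trait tables matching the published
# per-environment ranges and means for 384 wheat genotypes under fully
# irrigated (FI) and water-stressed (WS) regimes, and forward-modelled
# canopy reflectance whose chlorophyll, water and structure features
# co-vary with those traits. The goal is controllable statistical
# structure, not radiative-transfer realism.

#' Default trait generation parameters
#'
#' One row per trait x measurement stage x environment with the target
#' range (hard bounds) and mean/SD of the generated marginal distribution,
#' taken from the published field study (384 spring bread wheat genotypes,
#' two replicates, one season, two hydric regimes). LAI is measured under
#' FI only; Delta13C only at maturity.
#'
#' @return Tibble `trait`, `measurement_stage`, `environment`, `min`,
#'   `max`, `mean`, `sd`.
#' @export
default_trait_params <- function() {
  tribble_ <- function(...) {
    m <- matrix(c(...), ncol = 7, byrow = TRUE)
    tibble(trait = m[, 1], measurement_stage = m[, 2], environment = m[, 3],
           min = as.numeric(m[, 4]), max = as.numeric(m[, 5]),
           mean = as.numeric(m[, 6]), sd = as.numeric(m[, 7]))
  }
  tribble_(
    "SM2",  "m",  "FI", 320.0, 1125.0, 627.7, 133.7,
    "SM2",  "m",  "WS",  75.0,  625.0, 321.1,  69.3,
    "KPS",  "m",  "FI",  15.0,   68.9,  38.6,   6.5,
    "KPS",  "m",  "WS",   9.4,   55.6,  32.3,   6.3,
    "TKW",  "m",  "FI",  30.8,   88.6,  49.3,   6.6,
    "TKW",  "m",  "WS",  29.4,   89.4,  44.4,   6.8,
    "GY",   "m",  "FI",   5.1,   12.9,   9.7,   1.2,
    "GY",   "m",  "WS",   0.9,    6.9,   3.1,   0.9,
    "Chl",  "an", "FI",  35.9,   58.2,  49.3,   3.3,
    "Chl",  "an", "WS",  31.3,   52.0,  41.4,   3.5,
    "Chl",  "gf", "FI",  30.1,   56.0,  47.8,   3.7,
    "Chl",  "gf", "WS",   0.8,   48.8,  34.0,  10.3,
    "WSC",  "an", "FI",  16.1,  610.9, 141.2,  49.2,
    "WSC",  "an", "WS",  20.6,  708.4, 226.8,  51.7,
    "WSC",  "m",  "FI",   5.6,  686.3,  43.4,  33.3,
    "WSC",  "m",  "WS",   5.0,  218.3,  48.0,  23.5,
    "WSCC", "an", "FI",  19.3,  926.0, 172.1,  86.3,
    "WSCC", "an", "WS",  32.7, 1271.6, 410.8, 140.9,
    "WSCC", "m",  "FI",   6.1,  926.6,  47.4,  45.1,
    "WSCC", "m",  "WS",   4.9,  262.9,  52.1,  34.4,
    "D13C", "m",  "FI",  17.1,   20.2,  18.8,   0.5,
    "D13C", "m",  "WS",  12.3,   16.5,  14.9,   0.5,
    "LAI",  "an", "FI",   2.4,    8.4,   5.2,   1.0)
}

#' Carbon isotope discrimination
#'
#' \deqn{\Delta^{13}C (permil) = (\delta^{13}C_a - \delta^{13}C_p) /
#'   (1 + \delta^{13}C_p / 1000)}
#' where *a* and *p* denote air and plant. Values use the conventional
#' signed delta notation (air about -8 permil, plant delta more negative),
#' which is the only convention under which field Delta13C values of
#' 12--20 permil arise.
#'
#' @param delta13c_plant Plant delta13C in permil (signed).
#' @param delta13c_air Air delta13C in permil, default -8.0.
#' @return Discrimination in permil.
#' @export
#' @examples
#' delta13c(-27.0, -8.0)  # about 19.5, a well-watered value
delta13c <- function(delta13c_plant, delta13c_air = -8.0) {
  denom <- 1 + delta13c_plant / 1000
  if (any(denom == 0)) {
    abort("delta13c undefined: 1 + delta13c_plant/1000 is zero",
          class = "spectrait_domain_error")
  }
  (delta13c_air - delta13c_plant) / denom
}

# Invert the discrimination formula: the plant delta that yields a target
# discrimination at the given air delta.
delta13c_plant_for <- function(discrimination, delta13c_air = -8.0) {
  (delta13c_air - discrimination) / (1 + discrimination / 1000)
}

# Map a standard-normal latent to a scaled-Beta marginal with the target
# range, mean and sd. Beta tails keep the upper 20% of the *range* a
# genuinely small (but non-empty) class, unlike a uniform marginal.
scaled_beta_transform <- function(z, min, max, mean, sd) {
  m <- (mean - min) / (max - min)
  s <- sd / (max - min)
  s <- min(s, 0.95 * sqrt(m * (1 - m)))     # keep Beta feasible
  nu <- m * (1 - m) / s^2 - 1
  min + (max - min) * stats::qbeta(stats::pnorm(z), m * nu, (1 - m) * nu)
}

#' Generate a synthetic trait table
#'
#' Per genotype and trait, a latent genotype effect (correlated between FI
#' and WS at `env_correlation`, and across traits through a shared "vigor"
#' latent with weight `vigor_weight`) is combined with replicate noise
#' according to `genotype_share`, then mapped to a scaled-Beta marginal
#' with the per-environment range, mean and SD in `params`. Generated
#' values therefore honour the target ranges by construction (clip rate 0,
#' recorded in the `"clip_rate"` attribute). Delta13C is produced by
#' simulating plant delta13C and applying [delta13c()].
#'
#' @param n_genotypes Number of genotypes (default 384, the study size).
#' @param n_reps Replicates per genotype per environment (default 2).
#' @param params Target distributions; see [default_trait_params()].
#' @param genotype_share Fraction of latent variance attributable to
#'   genotype (vs replicate noise); default 0.7. `1` makes replicates of a
#'   genotype identical.
#' @param env_correlation Genotype-level FI/WS correlation, default 0.5.
#' @param vigor_weight Weight of the shared cross-trait genotype latent,
#'   default 0.5 (cross-trait genotype correlations of about 0.25).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return Long trait tibble `observation_id`, `genotype_id`,
#'   `environment`, `trait`, `measurement_stage`, `value`.
#' @export
generate_traits <- function(n_genotypes = 384, n_reps = 2,
                            params = default_trait_params(),
                            genotype_share = 0.7, env_correlation = 0.5,
                            vigor_weight = 0.5, seed = 1) {
  stopifnot(genotype_share >= 0, genotype_share <= 1,
            env_correlation >= 0, env_correlation <= 1,
            vigor_weight >= 0, vigor_weight < 1)
  if (any(params$min >= params$max) ||
      any(params$mean <= params$min | params$mean >= params$max)) {
    abort("trait params need min < mean < max",
          class = "spectrait_parameter_error")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  genos <- sprintf("G%03d", seq_len(n_genotypes))
  envs <- c("FI", "WS")
  rho <- env_correlation
  # shared vigor latent, per environment, correlated across environments
  vig_c <- stats::rnorm(n_genotypes)
  vig <- lapply(envs, function(e)
    sqrt(rho) * vig_c + sqrt(1 - rho) * stats::rnorm(n_genotypes))
  names(vig) <- envs
  traits_key <- unique(params[c("trait", "measurement_stage")])
  out <- list()
  for (i in seq_len(nrow(traits_key))) {
    tr <- traits_key$trait[i]; st <- traits_key$measurement_stage[i]
    g_c <- stats::rnorm(n_genotypes)
    for (e in envs) {
      row <- params[params$trait == tr & params$measurement_stage == st &
                      params$environment == e, ]
      if (nrow(row) == 0L) next
      g_env <- sqrt(rho) * g_c + sqrt(1 - rho) * stats::rnorm(n_genotypes)
      g <- vigor_weight * vig[[e]] + sqrt(1 - vigor_weight^2) * g_env
      for (r in seq_len(n_reps)) {
        z <- sqrt(genotype_share) * g +
          sqrt(1 - genotype_share) * stats::rnorm(n_genotypes)
        val <- scaled_beta_transform(z, row$min, row$max, row$mean, row$sd)
        if (tr == "D13C") {
          val <- delta13c(delta13c_plant_for(val))   # route through the formula
        }
        out[[length(out) + 1L]] <- tibble(
          observation_id = sprintf("%s_R%d_%s", genos, r, e),
          genotype_id = genos, environment = e,
          trait = tr, measurement_stage = st, value = val)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "clip_rate") <- 0
  validate_traits(res)
}

#' Spectral forward-model parameters
#'
#' The generator renders each plot's canopy spectrum as an LAI-style
#' mixture of smooth soil and vegetation endmembers, with Gaussian
#' absorption wells whose depths are affine in standardized trait drivers:
#' chlorophyll deepens the 670/490 nm pigment wells and shifts the red
#' edge; water status deepens the 970/1200/1450/1940 nm water wells;
#' canopy structure sets the soil/vegetation mixing weight. Setting a
#' coupling to 0 makes the corresponding spectral feature statistically
#' independent of its trait.
#'
#' @param coupling Named multipliers for `chlorophyll`, `water`,
#'   `structure`; 1 = the default "strong coupling" study condition.
#' @param drivers Traits standing behind each feature. Structure defaults
#'   to `GY` (canopy biomass proxy) because LAI is observed under FI only.
#' @param noise_sd Additive per-band Gaussian noise SD (reflectance
#'   fraction), default 0.004.
#' @param driver_noise SD of the plot-level mismatch added to each
#'   standardized driver (default 0.7). This models the physiological slack
#'   between a measured trait and its spectral expression: environment-scale
#'   contrasts (pooled-SD units ~ 2 between FI and WS) stay far above it,
#'   while within-environment trait variation (a fraction of a pooled SD)
#'   is partly masked, which is why pooled models outperform
#'   single-environment models.
#' @return Parameter list consumed by [generate_spectra()].
#' @export
spectral_forward_params <- function(coupling = c(chlorophyll = 1, water = 1,
                                                 structure = 1),
                                    drivers = list(chlorophyll = "Chl",
                                                   water = "D13C",
                                                   structure = "GY"),
                                    noise_sd = 0.004, driver_noise = 0.7) {
  list(coupling = coupling, drivers = drivers, noise_sd = noise_sd,
       driver_noise = driver_noise)
}

gaussian_well <- function(wl, center, width) exp(-((wl - center) / width)^2 / 2)

soil_endmember <- function(wl) 0.15 + 0.20 * (wl - 350) / 2150

vegetation_endmember <- function(wl, red_edge, chl_depth, water_depth) {
  v <- 0.04 +
    0.05 * gaussian_well(wl, 550, 25) +
    stats::plogis((wl - red_edge) / 20) *
      (0.18 + 0.30 * stats::plogis((1700 - wl) / 250))
  v <- v - chl_depth * (gaussian_well(wl, 670, 35) +
                          0.6 * gaussian_well(wl, 490, 25))
  v - water_depth * (0.50 * gaussian_well(wl, 970, 25) +
                       0.70 * gaussian_well(wl, 1200, 40) +
                       1.00 * gaussian_well(wl, 1450, 55) +
                       1.00 * gaussian_well(wl, 1940, 65))
}

std0 <- function(v) {
  s <- stats::sd(v[is.finite(v)])
  if (!is.finite(s) || s == 0) return(rep(0, length(v)))
  out <- (v - mean(v[is.finite(v)])) / s
  out[!is.finite(out)] <- 0
  out
}

#' Forward-model canopy spectra from a trait table
#'
#' One spectrum per plot per canopy stage on the full 350--2500 nm 1-nm
#' grid. Chlorophyll drivers follow the canopy stage (trait stage `an` for
#' spectra at `AN`, `gf` for `GF`); water and structure drivers are the
#' maturity traits. Drivers are standardized over the whole table (pooled
#' across environments), which is what gives pooled WS+FI data its larger
#' trait-signal range. Band noise is added and the result clamped to
#' \[0, 1\]; a parameter set pushing more than 10% of bands out of range
#' pre-clamp triggers a warning.
#'
#' @param traits Long trait tibble from [generate_traits()].
#' @param params See [spectral_forward_params()].
#' @param stages Canopy stages to render, default `c("AN", "GF")`.
#' @param seed Integer seed.
#' @return Spectra tibble with metadata `observation_id`, `plot_id`,
#'   `genotype_id`, `environment`, `stage` and bands `350`..`2500`.
#' @export
generate_spectra <- function(traits, params = spectral_forward_params(),
                             stages = c("AN", "GF"), seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  traits <- as_tibble(traits)
  plots <- unique(traits[c("observation_id", "genotype_id", "environment")])
  wl <- 350:2500
  cp <- params$coupling
  driver_of <- function(trait_name, stage_trait) {
    tt <- traits[traits$trait == trait_name &
                   traits$measurement_stage == stage_trait, ]
    v <- tt$value[match(plots$observation_id, tt$observation_id)]
    std0(v)
  }
  soil <- soil_endmember(wl)
  rows <- list()
  clipped <- 0; total <- 0
  dn <- if (is.null(params$driver_noise)) 0 else params$driver_noise
  for (st in stages) {
    chl <- driver_of(params$drivers$chlorophyll, if (st == "AN") "an" else "gf") +
      stats::rnorm(nrow(plots), sd = dn)
    wat <- driver_of(params$drivers$water, "m") +
      stats::rnorm(nrow(plots), sd = dn)
    str_ <- driver_of(params$drivers$structure, "m") +
      stats::rnorm(nrow(plots), sd = dn)
    refl <- matrix(0, nrow(plots), length(wl))
    for (i in seq_len(nrow(plots))) {
      veg <- vegetation_endmember(
        wl,
        red_edge = 715 + 5 * cp[["chlorophyll"]] * chl[i],
        chl_depth = max(0, 0.020 + 0.015 * cp[["chlorophyll"]] * chl[i]),
        water_depth = max(0, 0.10 + 0.05 * cp[["water"]] * wat[i]))
      f <- stats::plogis(0.8 + 0.8 * cp[["structure"]] * str_[i])
      r <- f * veg + (1 - f) * soil +
        stats::rnorm(length(wl), sd = params$noise_sd)
      clipped <- clipped + sum(r < 0 | r > 1); total <- total + length(r)
      refl[i, ] <- pmin(1, pmax(0, r))
    }
    colnames(refl) <- as.character(wl)
    rows[[st]] <- dplyr::bind_cols(
      tibble(observation_id = paste0(plots$observation_id, "_", st),
             plot_id = plots$observation_id,
             genotype_id = plots$genotype_id,
             environment = plots$environment,
             stage = st),
      as_tibble(as.data.frame(refl, check.names = FALSE)))
  }
  if (clipped / total > 0.10) {
    warn(sprintf("forward model clipped %.1f%% of band values to [0, 1]",
                 100 * clipped / total))
  }
  validate_spectra(dplyr::bind_rows(rows))
}

#' Small end-to-end benchmark fixture
#'
#' A reduced scene (64 genotypes x 2 replicates x 2 environments x 2
#' canopy stages = 512 spectra) with the default strong couplings, small
#' enough for the full pipeline to run in tests.
#'
#' @param seed Integer seed.
#' @param n_genotypes Scene size, default 64.
#' @return List with `spectra` and `traits` tibbles.
#' @export
make_benchmark_fixture <- function(seed = 1, n_genotypes = 64) {
  traits <- generate_traits(n_genotypes = n_genotypes, n_reps = 2, seed = seed)
  spectra <- generate_spectra(traits, seed = seed + 1)
  list(spectra = spectra, traits = traits)
}
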