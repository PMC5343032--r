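# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_abline labs facet_wrap theme_minimal
NULL

#' Plot canopy reflectance spectra
#'
#' One line per observation over the wavelength grid, coloured by
#' environment when present.
#'
#' @param spectra Spectra tibble.
#' @param max_obs At most this many observations are drawn (subsampled
#'   deterministically from the head of the table).
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, max_obs = 50) {
  spectra <- as_tibble(spectra)
  if (nrow(spectra) > max_obs) spectra <- spectra[seq_len(max_obs), ]
  bands <- band_cols(spectra)
  keep <- intersect(c("observation_id", "environment", "stage"),
                    names(spectra))
  long <- tidyr::pivot_longer(spectra[c(keep, bands)],
                              dplyr::all_of(bands),
                              names_to = "wavelength",
                              values_to = "reflectance")
  long$wavelength <- as.integer(long$wavelength)
  p <- ggplot(long, aes(x = .data$wavelength, y = .data$reflectance,
                        group = .data$observation_id))
  p <- if ("environment" %in% keep) {
    p + geom_line(aes(colour = .data$environment), alpha = 0.5)
  } else {
    p + geom_line(alpha = 0.5)
  }
  p + labs(x = "wavelength (nm)", y = "reflectance") + theme_minimal()
}

#' @rdname plot_spectra
#' @param object A `spectra_tbl`.
#' @param ... Passed to `plot_spectra()`.
#' @export
autoplot.spectra_tbl <- function(object, ...) plot_spectra(object, ...)

#' Observed versus predicted values of a trait regressor
#'
#' Out-of-fold (validation) predictions against observations, with the
#' identity line.
#'
#' @param object A fitted `trait_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trait_model <- function(object, ...) {
  df <- augment(object)
  g <- glance(object)
  ggplot(df, aes(x = .data$observed, y = .data$.oof)) +
    geom_point(alpha = 0.6) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = "observed", y = "out-of-fold prediction",
         title = sprintf("%s: validation R² = %.2f, RMSE = %.3g, IA = %.2f",
                         object$family, g$r2_val, g$rmse_val, g$ia_val)) +
    theme_minimal()
}

#' Ranked index screening plot
#'
#' Top indices by r-squared from [screen_indices()].
#'
#' @param object An `sri_screen` tibble.
#' @param top Number of indices to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sri_screen <- function(object, top = 15, ...) {
  df <- utils::head(as_tibble(object), top)
  df$index <- factor(df$index, levels = rev(df$index))
  ggplot(df, aes(x = .data$r2, y = .data$index)) +
    geom_col() +
    labs(x = expression(r^2), y = NULL,
         title = "Spectral index screening") +
    theme_minimal()
}

#' Benchmark summary plot
#'
#' Validation metric per method, faceted by environment set.
#'
#' @param object A `benchmark_result` tibble.
#' @param metric Metric to show (default `"r2"` for regressors).
#' @param split `"val"` (default) or `"cal"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.benchmark_result <- function(object, metric = "r2", split = "val",
                                      ...) {
  df <- dplyr::filter(as_tibble(object),
                      .data$metric == !!metric,
                      .data$split %in% c(!!split, "cal"),
                      .data$status == "ok")
  df <- dplyr::filter(df, .data$split == !!split |
                        .data$method == "sri")
  ggplot(df, aes(x = .data$method, y = .data$value,
                 fill = .data$spectra_stage)) +
    geom_col(position = "dodge") +
    facet_wrap(~ .data$trait + .data$environment) +
    labs(y = metric, x = NULL) + theme_minimal()
}
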