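# broom-style methods: tidy() for per-term/per-hyperparameter detail,
# glance() for one-row model summaries, augment() for per-observation
# predictions.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a fitted trait regressor
#'
#' For linear-form fits (PCR, PLSR, ridge) one row per feature with the
#' X-space coefficient; for SVR (no explicit coefficient vector) one row
#' per selected hyperparameter.
#'
#' @param x A `trait_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.trait_model <- function(x, ...) {
  if (!is.null(x$coefficients)) {
    dplyr::bind_rows(
      tibble(term = "(Intercept)", estimate = x$intercept),
      tibble(term = names(x$coefficients), estimate = unname(x$coefficients)))
  } else {
    tibble(term = names(x$selected),
           value = vapply(x$selected, function(v) paste(v, collapse = ","), ""))
  }
}

#' Summarise a fitted trait regressor in one row
#'
#' Calibration metrics come from the full-data refit (in-sample);
#' validation metrics from the out-of-fold predictions at the selected
#' hyperparameter.
#'
#' @param x A `trait_model`.
#' @param ... Unused.
#' @return One-row tibble: family, selected hyperparameter, `r2_cal`,
#'   `rmse_cal`, `ia_cal`, `r2_val`, `rmse_val`, `ia_val`, `n`.
#' @export
glance.trait_model <- function(x, ...) {
  cal <- regression_metrics(x$y, x$fitted)
  val <- regression_metrics(x$y, x$oof)
  tibble(family = x$family,
         selected = paste(names(x$selected),
                          vapply(x$selected, function(v)
                            paste(format(v, digits = 4), collapse = ","), ""),
                          sep = "=", collapse = "; "),
         r2_cal = cal$r2, rmse_cal = cal$rmse, ia_cal = cal$ia,
         r2_val = val$r2, rmse_val = val$rmse, ia_val = val$ia,
         n = length(x$y))
}

#' Per-observation predictions of a fitted trait regressor
#'
#' @param x A `trait_model`.
#' @param ... Unused.
#' @return Tibble with the observed response, in-sample fitted value,
#'   out-of-fold prediction and fold id per training observation.
#' @export
augment.trait_model <- function(x, ...) {
  tibble(observed = x$y, .fitted = x$fitted, .oof = x$oof, .fold = x$fold)
}

#' Tidy a fitted classifier
#'
#' One row per candidate hyperparameter value with its cross-validated
#' macro error rate.
#'
#' @param x A `trait_classifier`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.trait_classifier <- function(x, ...) x$cv

#' Summarise a fitted classifier in one row
#'
#' @param x A `trait_classifier`.
#' @param ... Unused.
#' @return One-row tibble with calibration and validation accuracy, macro
#'   error rate and per-class prediction rates.
#' @export
glance.trait_classifier <- function(x, ...) {
  cal <- classification_metrics(x$labels, x$fitted)
  val <- classification_metrics(x$labels, x$oof)
  tibble(family = x$family,
         selected = paste(names(x$selected), unlist(x$selected),
                          sep = "=", collapse = "; "),
         accuracy_cal = cal$accuracy, error_rate_cal = cal$error_rate,
         prediction_rate_class1_cal = cal$prediction_rate_class1,
         prediction_rate_class2_cal = cal$prediction_rate_class2,
         accuracy_val = val$accuracy, error_rate_val = val$error_rate,
         prediction_rate_class1_val = val$prediction_rate_class1,
         prediction_rate_class2_val = val$prediction_rate_class2,
         n = length(x$labels))
}

#' Per-observation labels of a fitted classifier
#'
#' @param x A `trait_classifier`.
#' @param ... Unused.
#' @return Tibble with the true label, in-sample label, out-of-fold label
#'   and fold id per training observation.
#' @export
augment.trait_classifier <- function(x, ...) {
  tibble(label = x$labels, .fitted = x$fitted, .oof = x$oof, .fold = x$fold)
}
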