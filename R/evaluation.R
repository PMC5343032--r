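# Cross-validation harness and all benchmark metrics: r-squared, RMSE,
# Willmott's Index of Agreement for regression; accuracy, macro error rate
# and per-class prediction rates for classification; plus the per-index
# linear screening used to rank spectral reflectance indices.

#' Seeded k-fold assignment
#'
#' Uniform random partition into `k` folds, optionally stratified so every
#' fold contains members of each stratum (used for classification, where an
#' unstratified split at 20% class prevalence risks folds with no elite
#' member).
#'
#' @param n Number of observations.
#' @param k Number of folds (default 10).
#' @param seed Integer seed; the same seed always yields the same folds.
#' @param strata Optional factor of length `n` for stratified assignment.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(n, k = 10, seed = 1, strata = NULL) {
  if (n < k) {
    abort(sprintf("n = %d observations cannot form k = %d folds; lower k", n, k),
          class = "spectrait_fold_error")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  fold <- integer(n)
  if (is.null(strata)) {
    fold <- sample(rep_len(seq_len(k), n))
  } else {
    strata <- as.factor(strata)
    for (lev in levels(strata)) {
      idx <- which(strata == lev)
      # rotate fold ids per stratum so small strata still spread over folds
      fold[idx] <- sample(rep_len(sample(k), length(idx)))
    }
  }
  fold
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generic k-fold cross-validation harness
#'
#' Each observation is predicted exactly once by a model that never saw it;
#' any preprocessing inside `trainer` is refit per fold, so fold statistics
#' never leak.
#'
#' @param x Predictor table.
#' @param y Response vector (numeric or factor).
#' @param trainer `function(x_train, y_train)` returning any model object.
#' @param predictor `function(model, x_new)` returning predictions.
#' @param k Number of folds.
#' @param seed Fold seed.
#' @param strata Optional stratification factor (see [make_folds()]).
#' @return A list with `predictions` (out-of-fold, input order), `fold`
#'   (fold ids) and `models` (per-fold fitted models).
#' @export
kfold_cv <- function(x, y, trainer, predictor = predict, k = 10, seed = 1,
                     strata = NULL) {
  x <- as.data.frame(x)
  n <- nrow(x)
  fold <- make_folds(n, k = k, seed = seed, strata = strata)
  pred <- rep(NA_real_, n)
  first <- TRUE
  models <- vector("list", k)
  for (f in sort(unique(fold))) {
    test <- fold == f
    m <- trainer(x[!test, , drop = FALSE], y[!test])
    p <- predictor(m, x[test, , drop = FALSE])
    if (first && (is.factor(p) || is.character(p))) {
      pred <- factor(rep(NA_character_, n), levels = levels(as.factor(y)))
      first <- FALSE
    }
    pred[test] <- p
    models[[f]] <- m
  }
  list(predictions = pred, fold = fold, models = models)
}

#' Willmott's Index of Agreement
#'
#' \deqn{d = 1 - \sum_i (P_i - O_i)^2 / \sum_i (|P_i - \bar O| + |O_i - \bar O|)^2}
#' A standardized measure of model prediction error ranging from 0 (faulty
#' model) to 1 (perfect fit). A prediction identically equal to the observed
#' mean scores exactly 0.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2);
#'   `observed` must not be constant.
#' @return Scalar in \[0, 1\].
#' @export
#' @examples
#' index_of_agreement(c(1, 2, 3), c(1, 2, 4))  # 1 - 1/13
index_of_agreement <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ok <- is.finite(observed) & is.finite(predicted)
  o <- observed[ok]; p <- predicted[ok]
  if (stats::sd(o) == 0) {
    abort("Index of Agreement undefined: observations are all identical",
          class = "spectrait_degenerate_error")
  }
  ob <- mean(o)
  denom <- sum((abs(p - ob) + abs(o - ob))^2)
  d <- 1 - sum((p - o)^2) / denom
  # the triangle inequality bounds d to [0, 1]; clamp the floating-point dust
  min(1, max(0, d))
}

#' Regression performance metrics
#'
#' `r2` is the squared Pearson correlation between observed and predicted
#' (invariant to affine transforms of the predictions), `rmse` the root
#' mean square error in trait units, and `ia` Willmott's Index of
#' Agreement.
#'
#' @inheritParams index_of_agreement
#' @return One-row tibble with columns `r2`, `rmse`, `ia`, `n`.
#' @export
regression_metrics <- function(observed, predicted) {
  ok <- is.finite(observed) & is.finite(predicted)
  o <- observed[ok]; p <- predicted[ok]
  r2 <- if (stats::sd(o) == 0 || stats::sd(p) == 0) NA_real_
        else stats::cor(o, p)^2
  tibble(r2 = r2,
         rmse = sqrt(mean((o - p)^2)),
         ia = index_of_agreement(o, p),
         n = length(o))
}

#' Classification performance metrics
#'
#' Accuracy is the overall fraction correct. Prediction rates are per-class
#' sensitivities (class-wise recall). The canonical `error_rate` is
#' 1 minus the macro-averaged class sensitivity, which is the definition
#' under which high accuracy can coexist with a high error rate when the
#' minority class is poorly recovered; `error_rate_overall = 1 - accuracy`
#' is reported alongside. The two coincide exactly for balanced classes.
#'
#' @param labels True labels over `{Class1, Class2}` (factor or character).
#' @param predicted_labels Predicted labels over the same set.
#' @return One-row tibble with `accuracy`, `error_rate` (macro),
#'   `error_rate_overall`, `prediction_rate_class1`,
#'   `prediction_rate_class2`, `n`, and the 2x2 `confusion` counts as a
#'   list column.
#' @export
classification_metrics <- function(labels, predicted_labels) {
  lv <- c("Class1", "Class2")
  labels <- as.character(labels); predicted_labels <- as.character(predicted_labels)
  bad <- setdiff(stats::na.omit(unique(c(labels, predicted_labels))), lv)
  if (length(bad) > 0L) {
    abort(sprintf("unexpected label value(s): %s", paste(bad, collapse = ", ")),
          class = "spectrait_schema_error")
  }
  ok <- !is.na(labels) & !is.na(predicted_labels)
  truth <- factor(labels[ok], levels = lv)
  est <- factor(predicted_labels[ok], levels = lv)
  if (any(table(truth) == 0L)) {
    abort("both true classes must be present to compute class-wise rates",
          class = "spectrait_degenerate_error")
  }
  cm <- table(truth = truth, predicted = est)
  rate1 <- cm["Class1", "Class1"] / sum(cm["Class1", ])
  rate2 <- cm["Class2", "Class2"] / sum(cm["Class2", ])
  acc <- sum(diag(cm)) / sum(cm)
  tibble(accuracy = acc,
         error_rate = 1 - (rate1 + rate2) / 2,
         error_rate_overall = 1 - acc,
         prediction_rate_class1 = unname(rate1),
         prediction_rate_class2 = unname(rate2),
         n = sum(cm),
         confusion = list(cm))
}

#' Screen spectral indices against a trait by simple linear regression
#'
#' Fits ordinary least squares `trait ~ index` for every index column and
#' ranks the indices by validation-free in-sample fit: descending r-squared,
#' ties broken by ascending RMSE then name. This is the classical
#' index-screening step run before (and compared against) full-spectrum
#' multivariate models.
#'
#' @param index_table Tibble from [compute_indices()]: `observation_id`
#'   plus one numeric column per index.
#' @param trait_values Numeric response aligned to the rows.
#' @param min_n Minimum paired observations for an index to be screened.
#' @return Tibble `index`, `slope`, `intercept`, `r2`, `rmse`, `n`, ranked;
#'   all-missing index columns are excluded with a note in the
#'   `"n_excluded"` attribute. The number of indices screened is recorded in
#'   the `"n_tested"` attribute (no multiplicity correction is applied).
#' @export
screen_indices <- function(index_table, trait_values, min_n = 3) {
  idx_cols <- setdiff(names(index_table), "observation_id")
  rows <- lapply(idx_cols, function(nm) {
    v <- index_table[[nm]]
    ok <- is.finite(v) & is.finite(trait_values)
    if (sum(ok) < min_n || stats::sd(v[ok]) == 0) return(NULL)
    fit <- stats::lm.fit(cbind(1, v[ok]), trait_values[ok])
    res <- fit$residuals
    tss <- sum((trait_values[ok] - mean(trait_values[ok]))^2)
    tibble(index = nm, slope = unname(fit$coefficients[2L]),
           intercept = unname(fit$coefficients[1L]),
           r2 = if (tss == 0) NA_real_ else 1 - sum(res^2) / tss,
           rmse = sqrt(mean(res^2)), n = sum(ok))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    abort("no index had enough paired observations to screen",
          class = "spectrait_empty_error")
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$r2), .data$rmse, .data$index)
  attr(out, "n_tested") <- nrow(out)
  attr(out, "n_excluded") <- length(idx_cols) - nrow(out)
  class(out) <- unique(c("sri_screen", class(out)))
  out
}
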