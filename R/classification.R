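# Elite-genotype classification: trait values are dichotomized on the
# observed range (lower 80% of the range = Class1, upper 20% = Class2, the
# elite group), then three categorical models are tuned by stratified
# 10-fold cross-validation minimizing the macro error rate. All classifiers
# mean-centre their inputs, the only normalization the protocol specifies
# for the categorical family.

#' Range-based elite dichotomization
#'
#' Splits observations at `threshold = min + fraction * (max - min)`
#' computed over the supplied values: values below the threshold are
#' `Class1`, values at or above it are `Class2` (the elite group; a value
#' exactly on the threshold counts as elite). Labels are invariant to
#' increasing affine transforms of the trait. The threshold belongs to the
#' dataset it is computed on, so pooled environments (WS+FI) yield a
#' different threshold than either environment alone.
#'
#' @param values Numeric trait values (at least two distinct).
#' @param fraction Lower-range fraction assigned to `Class1`;
#'   default 0.80.
#' @return A `class_labeling` list: `labels` (factor `Class1`/`Class2`),
#'   `threshold`, `fraction`, `range`.
#' @export
#' @examples
#' dichotomize(1:10)$labels   # 1..8 -> Class1, 9..10 -> Class2
dichotomize <- function(values, fraction = 0.8) {
  stopifnot(fraction > 0, fraction < 1)
  ok <- is.finite(values)
  rng <- range(values[ok])
  if (diff(rng) == 0) {
    abort("all trait values identical: range-based dichotomization undefined",
          class = "spectrait_degenerate_error")
  }
  threshold <- rng[1L] + fraction * diff(rng)
  labels <- factor(ifelse(values >= threshold, "Class2", "Class1"),
                   levels = c("Class1", "Class2"))
  labels[!ok] <- NA
  if (any(table(labels) == 0L)) {
    abort("dichotomization left one class empty", # can occur for fraction ~ 0/1
          class = "spectrait_degenerate_error")
  }
  structure(list(labels = labels, threshold = threshold,
                 fraction = fraction, range = rng),
            class = "class_labeling")
}

#' @export
print.class_labeling <- function(x, ...) {
  cat(sprintf("<class_labeling> threshold %.4g (fraction %.2f of range [%.4g, %.4g])\n",
              x$threshold, x$fraction, x$range[1L], x$range[2L]))
  print(table(x$labels))
  invisible(x)
}

check_two_classes <- function(labels) {
  labels <- factor(as.character(labels), levels = c("Class1", "Class2"))
  if (any(is.na(labels))) {
    abort("labels must be Class1/Class2 with no NA",
          class = "spectrait_schema_error")
  }
  if (any(table(labels) == 0L)) {
    abort("both classes must be present", class = "spectrait_degenerate_error")
  }
  labels
}

new_classifier <- function(family, subclass, features, labels, fitted, oof,
                           fold, cv, selected, extra = list()) {
  structure(c(list(family = family, features = features, labels = labels,
                   fitted = fitted, oof = oof, fold = fold, cv = cv,
                   selected = selected), extra),
            class = c(subclass, "trait_classifier"))
}

macro_error <- function(truth, est) {
  cm <- table(factor(truth, levels = c("Class1", "Class2")),
              factor(est, levels = c("Class1", "Class2")))
  1 - mean(diag(cm) / rowSums(cm))
}

# Shared tuning loop: stratified folds, out-of-fold label matrix over the
# hyperparameter grid, selection by macro error rate (smallest value wins
# ties, i.e. the simpler model).
tune_classifier <- function(xm, labels, grid, fold, fit_predict) {
  n <- nrow(xm)
  oof <- matrix(NA_character_, n, length(grid))
  for (f in sort(unique(fold))) {
    te <- fold == f
    preds <- fit_predict(xm[!te, , drop = FALSE], labels[!te],
                         xm[te, , drop = FALSE], grid)
    for (j in seq_along(grid)) oof[te, j] <- preds[[j]]
  }
  err <- vapply(seq_along(grid), function(j) macro_error(labels, oof[, j]), 0)
  sel <- which.min(err)
  list(oof = factor(oof[, sel], levels = c("Class1", "Class2")),
       cv = tibble(parameter = grid, cv_error_rate = err), sel = sel)
}

#' PCA-LDA classifier
#'
#' Principal component scores of the mean-centred spectra feed a linear
#' discriminant (class means with pooled covariance, via
#' \code{MASS::lda}). The number of components is searched over
#' 1--`max_pc` by stratified 10-fold cross-validation minimizing the macro
#' error rate; PCA and the discriminant are refit inside every fold.
#'
#' @param x Predictor data frame (mean-centred or raw; centring is fit
#'   internally and replayed at prediction).
#' @param labels `Class1`/`Class2` labels (factor/character) or a
#'   [dichotomize()] result.
#' @param max_pc Upper end of the component search (default 20).
#' @param cv_folds,seed Cross-validation folds and seed.
#' @return A `pca_lda_fit` / `trait_classifier` object.
#' @export
fit_pca_lda <- function(x, labels, max_pc = 20, cv_folds = 10, seed = 1) {
  if (inherits(labels, "class_labeling")) labels <- labels$labels
  labels <- check_two_classes(labels)
  x <- as.data.frame(x)
  features <- names(x)
  xm <- as.matrix(x)
  grid <- seq_len(min(max_pc, nrow(xm) - 2L, ncol(xm)))
  fold <- make_folds(nrow(xm), k = cv_folds, seed = seed, strata = labels)
  fit_predict <- function(xtr, ytr, xte, grid) {
    ctr <- colMeans(xtr)
    sv <- svd(sweep(xtr, 2L, ctr))
    r <- sum(sv$d > max(sv$d[1L], 1) * 1e-10)
    str <- sv$u * rep(sv$d, each = nrow(xtr))
    ste <- sweep(xte, 2L, ctr) %*% sv$v
    lapply(grid, function(a) {
      a <- min(a, r)
      ld <- MASS::lda(str[, seq_len(a), drop = FALSE], grouping = ytr)
      as.character(stats::predict(ld, ste[, seq_len(a), drop = FALSE])$class)
    })
  }
  tuned <- tune_classifier(xm, labels, grid, fold, fit_predict)
  ctr <- colMeans(xm)
  sv <- svd(sweep(xm, 2L, ctr))
  a <- min(grid[tuned$sel], sum(sv$d > max(sv$d[1L], 1) * 1e-10))
  scores <- (sv$u * rep(sv$d, each = nrow(xm)))[, seq_len(a), drop = FALSE]
  ld <- MASS::lda(scores, grouping = labels)
  fitted <- stats::predict(ld, scores)$class
  new_classifier(
    "PCA-LDA", "pca_lda_fit", features, labels, fitted = fitted,
    oof = tuned$oof, fold = fold,
    cv = dplyr::rename(tuned$cv, n_pc = "parameter"),
    selected = list(n_pc = a),
    extra = list(center = ctr, rotation = sv$v[, seq_len(a), drop = FALSE],
                 lda = ld))
}

# PLS-DA scores for the 0/1 elite indicator, for each latent-variable count.
plsda_scores <- function(xtr, ytr, xte, grid) {
  ctr <- colMeans(xtr)
  y01 <- as.numeric(ytr == "Class2")
  ft <- nipals_pls1(sweep(xtr, 2L, ctr), y01 - mean(y01), max(grid))
  betas <- pls_betas(ft)
  xc <- sweep(xte, 2L, ctr)
  lapply(grid, function(a) {
    a2 <- min(a, ft$ncomp)
    as.numeric(xc %*% betas[[a2]]) + mean(y01)
  })
}

# Class-conditional Gaussian calibration of PLS-DA scores: fit N(mu_c, sd_c)
# to the calibration scores of each true class, assign by maximum posterior.
plsda_assign <- function(score, cal_scores, cal_labels, rule, priors) {
  if (rule == "argmax") {
    return(ifelse(score >= 0.5, "Class2", "Class1"))
  }
  mu <- tapply(cal_scores, cal_labels, mean)
  sd_ <- tapply(cal_scores, cal_labels, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- stats::sd(cal_scores) + 1e-12
  p1 <- priors["Class1"] * stats::dnorm(score, mu["Class1"], sd_["Class1"])
  p2 <- priors["Class2"] * stats::dnorm(score, mu["Class2"], sd_["Class2"])
  ifelse(p2 > p1, "Class2", "Class1")
}

#' PLS-DA classifier
#'
#' PLS regression of the elite-class indicator on the mean-centred
#' spectra; the latent-variable count is searched over 1--`max_lv` by
#' stratified 10-fold cross-validation minimizing the macro error rate.
#' Class assignment fits class-conditional Gaussians to the calibration
#' scores of each class and assigns by maximum posterior (`rule =
#' "gaussian"`, the chemometrics-toolbox convention); `rule = "argmax"`
#' simply thresholds the predicted indicator at 0.5. Posterior priors are
#' equal by default so the minority elite class is recoverable; set
#' `priors = "proportional"` for training-frequency priors.
#'
#' @inheritParams fit_pca_lda
#' @param max_lv Upper end of the latent-variable search (default 20).
#' @param rule `"gaussian"` or `"argmax"`.
#' @param priors `"equal"` or `"proportional"`.
#' @return A `plsda_fit` / `trait_classifier` object.
#' @export
fit_plsda <- function(x, labels, max_lv = 20, rule = c("gaussian", "argmax"),
                      priors = c("equal", "proportional"), cv_folds = 10,
                      seed = 1) {
  rule <- match.arg(rule); priors <- match.arg(priors)
  if (inherits(labels, "class_labeling")) labels <- labels$labels
  labels <- check_two_classes(labels)
  x <- as.data.frame(x)
  features <- names(x)
  xm <- as.matrix(x)
  grid <- seq_len(min(max_lv, nrow(xm) - 2L, ncol(xm)))
  fold <- make_folds(nrow(xm), k = cv_folds, seed = seed, strata = labels)
  pri <- if (priors == "equal") c(Class1 = 0.5, Class2 = 0.5)
         else prop.table(table(labels))[c("Class1", "Class2")]
  fit_predict <- function(xtr, ytr, xte, grid) {
    ste <- plsda_scores(xtr, ytr, xte, grid)
    str <- plsda_scores(xtr, ytr, xtr, grid)
    lapply(seq_along(grid), function(j) {
      plsda_assign(ste[[j]], str[[j]], ytr, rule, pri)
    })
  }
  tuned <- tune_classifier(xm, labels, grid, fold, fit_predict)
  sel <- grid[tuned$sel]
  ctr <- colMeans(xm)
  y01 <- as.numeric(labels == "Class2")
  ft <- nipals_pls1(sweep(xm, 2L, ctr), y01 - mean(y01), sel)
  beta <- pls_betas(ft)[[ft$ncomp]]
  cal_scores <- as.numeric(sweep(xm, 2L, ctr) %*% beta) + mean(y01)
  fitted <- factor(plsda_assign(cal_scores, cal_scores, labels, rule, pri),
                   levels = c("Class1", "Class2"))
  new_classifier(
    "PLS-DA", "plsda_fit", features, labels, fitted = fitted,
    oof = tuned$oof, fold = fold,
    cv = dplyr::rename(tuned$cv, n_lv = "parameter"),
    selected = list(n_lv = ft$ncomp, rule = rule),
    extra = list(center = ctr, beta = beta, intercept = mean(y01),
                 cal_scores = cal_scores, priors = pri))
}

# Deterministic kNN: distance ties broken by training order (stable sort),
# majority-vote ties by the label of the nearest neighbour overall.
knn_predict_matrix <- function(xtr, ytr, xte, k) {
  apply_one <- function(q) {
    d <- sqrt(colSums((t(xtr) - q)^2))
    ord <- order(d)                     # stable: ties keep training order
    nn <- ord[seq_len(k)]
    votes <- table(factor(as.character(ytr[nn]),
                          levels = c("Class1", "Class2")))
    if (votes["Class1"] == votes["Class2"]) as.character(ytr[nn[1L]])
    else names(which.max(votes))
  }
  vapply(seq_len(nrow(xte)), function(i) apply_one(xte[i, ]), "")
}

#' k-nearest-neighbour classifier
#'
#' Euclidean kNN with majority voting on mean-centred spectra. `k` is
#' searched over 1--`max_k` by stratified 10-fold cross-validation
#' minimizing the macro error rate. Predictions are fully deterministic:
#' distance ties are broken by training-set order (stable sort) and vote
#' ties by the nearer neighbour's label.
#'
#' @inheritParams fit_pca_lda
#' @param max_k Upper end of the neighbourhood search (default 10).
#' @return A `knn_fit` / `trait_classifier` object.
#' @export
fit_knn <- function(x, labels, max_k = 10, cv_folds = 10, seed = 1) {
  if (inherits(labels, "class_labeling")) labels <- labels$labels
  labels <- check_two_classes(labels)
  x <- as.data.frame(x)
  features <- names(x)
  xm <- as.matrix(x)
  if (any(!is.finite(xm))) {
    abort("kNN requires finite features", class = "spectrait_input_error")
  }
  grid <- seq_len(min(max_k, nrow(xm) - 2L))
  fold <- make_folds(nrow(xm), k = cv_folds, seed = seed, strata = labels)
  ctr <- colMeans(xm)
  fit_predict <- function(xtr, ytr, xte, grid) {
    lapply(grid, function(k) knn_predict_matrix(xtr, ytr, xte, k))
  }
  xc <- sweep(xm, 2L, ctr)
  tuned <- tune_classifier(xc, labels, grid, fold, fit_predict)
  k_sel <- grid[tuned$sel]
  fitted <- factor(knn_predict_matrix(xc, labels, xc, k_sel),
                   levels = c("Class1", "Class2"))
  new_classifier(
    "kNN", "knn_fit", features, labels, fitted = fitted,
    oof = tuned$oof, fold = fold,
    cv = dplyr::rename(tuned$cv, k = "parameter"),
    selected = list(k = k_sel),
    extra = list(center = ctr, x_train = xc, y_train = labels))
}

#' Predict class labels from a fitted classifier
#'
#' Features are aligned by name (column order in `new_data` is
#' irrelevant); the stored mean-centring is replayed before prediction.
#'
#' @param object A fitted `trait_classifier`.
#' @param new_data Data frame carrying the training feature set.
#' @param ... Unused.
#' @return Factor of `Class1`/`Class2` labels.
#' @export
predict.trait_classifier <- function(object, new_data, ...) {
  xm <- as_feature_matrix(new_data, object$features)
  if (any(!is.finite(xm))) {
    abort("prediction requires finite features", class = "spectrait_input_error")
  }
  xc <- sweep(xm, 2L, object$center)
  out <- switch(
    object$family,
    "PCA-LDA" = as.character(
      stats::predict(object$lda, xc %*% object$rotation)$class),
    "PLS-DA" = {
      s <- as.numeric(xc %*% object$beta) + object$intercept
      plsda_assign(s, object$cal_scores, object$labels,
                   object$selected$rule, object$priors)
    },
    "kNN" = knn_predict_matrix(object$x_train, object$y_train, xc,
                               object$selected$k),
    abort("unknown classifier family"))
  factor(out, levels = c("Class1", "Class2"))
}

#' @export
print.trait_classifier <- function(x, ...) {
  cat(sprintf("<%s classifier> %d features, n = %d\n", x$family,
              length(x$features), length(x$labels)))
  cat("selected:", paste(names(x$selected), unlist(x$selected),
                         sep = " = ", collapse = ", "), "\n")
  g <- generics::glance(x)
  cat(sprintf("validation: accuracy %.3f, macro error %.3f, class rates %.2f / %.2f\n",
              g$accuracy_val, g$error_rate_val,
              g$prediction_rate_class1_val, g$prediction_rate_class2_val))
  invisible(x)
}
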