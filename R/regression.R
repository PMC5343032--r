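# The four multivariate regressors compared in the benchmark. All take a
# predictor data frame plus a numeric response, tune their single
# hyperparameter by seeded 10-fold cross-validated RMSE, refit on all data
# at the selected value, and keep the out-of-fold predictions at that value
# as the validation set. Predictors are assumed already normalized by the
# preprocessing pipeline; each fit still centres internally so an intercept
# is always handled.

as_feature_matrix <- function(x, features) {
  x <- as.data.frame(x)
  miss <- setdiff(features, names(x))
  if (length(miss) > 0L) {
    abort(sprintf("new data is missing feature(s): %s",
                  paste(utils::head(miss, 5), collapse = ", ")),
          class = "spectrait_schema_error")
  }
  as.matrix(x[features])
}

new_trait_model <- function(family, subclass, features, y, coef = NULL,
                            intercept = NULL, fitted, oof, fold, cv, selected,
                            extra = list()) {
  structure(c(list(family = family, features = features, y = y,
                   coefficients = coef, intercept = intercept,
                   fitted = fitted, oof = oof, fold = fold,
                   cv = cv, selected = selected), extra),
            class = c(subclass, "trait_model"))
}

#' The ridge penalty grid
#'
#' 100 values of \eqn{\lambda} log-spaced over \eqn{[10^{-2}, 10^{10}]},
#' the grid searched by 10-fold cross-validation in the benchmark protocol.
#'
#' @return Strictly increasing numeric vector of length 100.
#' @export
ridge_lambda_grid <- function() 10^seq(-2, 10, length.out = 100)

# Closed-form ridge coefficients for every lambda from one SVD.
ridge_solve <- function(xtr, ytr, xte, lambda) {
  xm <- colMeans(xtr); ym <- mean(ytr)
  xc <- sweep(xtr, 2L, xm)
  sv <- svd(xc)
  w <- crossprod(sv$u, ytr - ym)[, 1L]          # U'y
  mte <- sweep(xte, 2L, xm) %*% sv$v            # scores of test rows
  pred <- vapply(lambda, function(l) {
    as.numeric(mte %*% (sv$d * w / (sv$d^2 + l))) + ym
  }, numeric(nrow(xte)))
  list(pred = matrix(pred, nrow = nrow(xte)),
       beta = function(l) as.numeric(sv$v %*% (sv$d * w / (sv$d^2 + l))),
       xm = xm, ym = ym)
}

#' Ridge regression over a cross-validated lambda grid
#'
#' Penalized least squares \eqn{\min \|y - X\beta\|^2 + \lambda\|\beta\|^2}
#' solved in closed form (one SVD serves the whole grid). The grid of 100
#' log-spaced penalties over \eqn{[10^{-2}, 10^{10}]} is searched by
#' 10-fold cross-validated RMSE; the best \eqn{\lambda} is refit on all
#' data. Ridge shrinks coefficients toward zero and is defined for any
#' \eqn{\lambda > 0} even when `x` is singular (p > n).
#'
#' @param x Predictor data frame (rows = observations).
#' @param y Numeric response.
#' @param lambda_grid Penalty grid, default [ridge_lambda_grid()].
#' @param cv_folds Number of CV folds (default 10).
#' @param seed Fold seed.
#' @return A `ridge_fit` / `trait_model` object; see [glance.trait_model()].
#' @export
fit_ridge <- function(x, y, lambda_grid = ridge_lambda_grid(), cv_folds = 10,
                      seed = 1) {
  x <- as.data.frame(x)
  features <- names(x)
  xm <- as.matrix(x)
  fold <- make_folds(nrow(xm), k = cv_folds, seed = seed)
  oof <- matrix(NA_real_, nrow(xm), length(lambda_grid))
  for (f in sort(unique(fold))) {
    te <- fold == f
    rs <- ridge_solve(xm[!te, , drop = FALSE], y[!te],
                      xm[te, , drop = FALSE], lambda_grid)
    oof[te, ] <- rs$pred
  }
  cv_rmse <- sqrt(colMeans((oof - y)^2))
  sel <- which.min(cv_rmse)
  full <- ridge_solve(xm, y, xm, lambda_grid[sel])
  beta <- full$beta(lambda_grid[sel])
  names(beta) <- features
  intercept <- full$ym - sum(full$xm * beta)
  new_trait_model(
    "RR", "ridge_fit", features, y, coef = beta, intercept = intercept,
    fitted = as.numeric(full$pred), oof = oof[, sel],
    fold = fold,
    cv = tibble(lambda = lambda_grid, cv_rmse = cv_rmse),
    selected = list(lambda = lambda_grid[sel]))
}

# NIPALS PLS1: returns weights W, loadings P, y-loadings q for up to A
# latent factors, with X deflated after each factor.
nipals_pls1 <- function(xc, yc, A) {
  p <- ncol(xc)
  W <- matrix(0, p, A); P <- matrix(0, p, A); q <- numeric(A)
  a <- 0L
  for (i in seq_len(A)) {
    w <- crossprod(xc, yc)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- xc %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pl <- crossprod(xc, t)[, 1L] / tt
    qa <- sum(yc * t) / tt
    xc <- xc - t %*% t(pl)
    yc <- yc - qa * t
    a <- i
    W[, i] <- w; P[, i] <- pl; q[i] <- qa
  }
  list(W = W[, seq_len(a), drop = FALSE], P = P[, seq_len(a), drop = FALSE],
       q = q[seq_len(a)], ncomp = a)
}

# X-space coefficient vectors for 1..A PLS factors: B_a = W_a (P_a'W_a)^-1 q_a
pls_betas <- function(fit) {
  lapply(seq_len(fit$ncomp), function(a) {
    Wa <- fit$W[, seq_len(a), drop = FALSE]
    Pa <- fit$P[, seq_len(a), drop = FALSE]
    as.numeric(Wa %*% solve(crossprod(Pa, Wa), fit$q[seq_len(a)]))
  })
}

component_fit <- function(x, y, family, max_components, cv_folds, seed) {
  x <- as.data.frame(x)
  features <- names(x)
  xm <- as.matrix(x)
  n <- nrow(xm)
  if (stats::sd(y) == 0) {
    abort("response has zero variance (degenerate response)",
          class = "spectrait_degenerate_error")
  }
  A <- min(max_components, n - 2L, ncol(xm))
  fold <- make_folds(n, k = cv_folds, seed = seed)
  oof <- matrix(NA_real_, n, A)
  betas_for <- function(xtr, ytr, A_local) {
    xmn <- colMeans(xtr); ymn <- mean(ytr)
    xc <- sweep(xtr, 2L, xmn); yc <- ytr - ymn
    if (family == "PLSR") {
      ft <- nipals_pls1(xc, yc, A_local)
      list(betas = pls_betas(ft), xmn = xmn, ymn = ymn, ncomp = ft$ncomp)
    } else {
      pc <- svd(xc)
      r <- sum(pc$d > max(pc$d[1L], 1) * 1e-10)
      a_max <- min(A_local, r)
      scores <- pc$u[, seq_len(a_max), drop = FALSE] *
        rep(pc$d[seq_len(a_max)], each = nrow(xc))
      gamma <- as.numeric(crossprod(scores, yc)) / colSums(scores^2)
      betas <- lapply(seq_len(a_max), function(a) {
        as.numeric(pc$v[, seq_len(a), drop = FALSE] %*% gamma[seq_len(a)])
      })
      list(betas = betas, xmn = xmn, ymn = ymn, ncomp = a_max)
    }
  }
  for (f in sort(unique(fold))) {
    te <- fold == f
    bf <- betas_for(xm[!te, , drop = FALSE], y[!te], A)
    xte <- sweep(xm[te, , drop = FALSE], 2L, bf$xmn)
    for (a in seq_len(bf$ncomp)) {
      oof[te, a] <- as.numeric(xte %*% bf$betas[[a]]) + bf$ymn
    }
  }
  usable <- which(colSums(is.na(oof)) == 0L)
  cv_rmse <- vapply(usable, function(a) sqrt(mean((oof[, a] - y)^2)), 0)
  sel <- usable[which.min(cv_rmse)]
  bf <- betas_for(xm, y, A)
  if (bf$ncomp < sel) {
    warn(sprintf("%s: requested %d components exceeds rank; using %d",
                 family, sel, bf$ncomp))
    sel <- bf$ncomp
  }
  beta <- bf$betas[[sel]]
  names(beta) <- features
  intercept <- bf$ymn - sum(bf$xmn * beta)
  new_trait_model(
    family, if (family == "PLSR") "plsr_fit" else "pcr_fit",
    features, y, coef = beta, intercept = intercept,
    fitted = as.numeric(xm %*% beta) + intercept, oof = oof[, sel],
    fold = fold,
    cv = tibble(ncomp = usable, cv_rmse = cv_rmse),
    selected = list(ncomp = sel))
}

#' Principal component regression
#'
#' PCA on the centred predictors followed by ordinary least squares of the
#' response on the leading scores; the component count (searched over
#' 1--`max_components` by 10-fold cross-validated RMSE) is the only
#' hyperparameter. Coefficients are mapped back to the original feature
#' space, so predictions are invariant to component sign flips. A request
#' beyond the rank of `x` is reduced to the rank with a warning.
#'
#' @inheritParams fit_ridge
#' @param max_components Upper end of the component search range
#'   (default 20).
#' @return A `pcr_fit` / `trait_model` object.
#' @export
fit_pcr <- function(x, y, max_components = 20, cv_folds = 10, seed = 1) {
  component_fit(x, y, "PCR", max_components, cv_folds, seed)
}

#' Partial least squares regression
#'
#' NIPALS PLS1: latent factors chosen to maximize covariance with the
#' response, with X deflation after each factor. The factor count is
#' searched over 1--`max_components` by 10-fold cross-validated RMSE. At
#' full rank PLSR reproduces ordinary least squares.
#'
#' @inheritParams fit_pcr
#' @return A `plsr_fit` / `trait_model` object.
#' @export
fit_plsr <- function(x, y, max_components = 20, cv_folds = 10, seed = 1) {
  component_fit(x, y, "PLSR", max_components, cv_folds, seed)
}

#' Median-heuristic kernel scale
#'
#' \eqn{\gamma = 1 / \mathrm{median}(\|x_i - x_j\|^2)} over (a subsample
#' of) the training rows; the standard default scale for radial-basis
#' kernels.
#'
#' @param x Numeric matrix or data frame.
#' @param max_rows Subsample cap for the pairwise distance computation.
#' @param seed Subsample seed.
#' @return Positive scalar.
#' @export
median_heuristic_gamma <- function(x, max_rows = 200, seed = 1) {
  x <- as.matrix(x)
  if (nrow(x) > max_rows) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    x <- x[sample(nrow(x), max_rows), , drop = FALSE]
  }
  d2 <- stats::dist(x)^2
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m == 0) 1 else 1 / m
}

#' Support vector regression with automatic kernel selection
#'
#' Epsilon-insensitive SVR (via \pkg{e1071}) with the regularization
#' parameter fixed at `C = 1` and the loss tube at `epsilon = 0.1`. The
#' response is standardized internally (so the fixed `C` and `epsilon` are
#' meaningful across trait units, the usual libsvm convention) and
#' predictions are returned on the original scale. Each
#' candidate kernel (linear, polynomial of degree 3, radial basis,
#' sigmoid) is trained under the same seeded 10-fold cross-validation; the
#' kernel with the minimum CV RMSE is selected and refit on all data.
#' Kernel scale for the nonlinear kernels comes from the median heuristic.
#' A kernel whose training fails is skipped with a warning.
#'
#' @inheritParams fit_ridge
#' @param kernels Candidate kernels to test.
#' @param cost,epsilon SVR parameters, fixed to 1 and 0.1 by default.
#' @param ... Further arguments passed to [e1071::svm()] (e.g. `tolerance`).
#' @return An `svr_fit` / `trait_model` object.
#' @export
fit_svr <- function(x, y, kernels = c("linear", "polynomial", "radial",
                                      "sigmoid"),
                    cost = 1, epsilon = 0.1, cv_folds = 10, seed = 1, ...) {
  x <- as.data.frame(x)
  features <- names(x)
  xm <- as.matrix(x)
  ym <- mean(y)
  ys <- sqrt(mean((y - ym)^2))   # population SD: invariant to row duplication
  if (!is.finite(ys) || ys == 0) ys <- 1
  yz <- (y - ym) / ys
  gamma <- median_heuristic_gamma(xm, seed = seed)
  fold <- make_folds(nrow(xm), k = cv_folds, seed = seed)
  extra_args <- list(...)
  svm_args <- function(kernel) {
    c(list(type = "eps-regression", kernel = kernel, cost = cost,
           epsilon = epsilon, gamma = gamma, degree = 3, scale = FALSE),
      extra_args)
  }
  oof <- matrix(NA_real_, nrow(xm), length(kernels))
  colnames(oof) <- kernels
  for (kern in kernels) {
    ok <- tryCatch({
      for (f in sort(unique(fold))) {
        te <- fold == f
        # response re-standardized on the training fold only
        mtr <- mean(yz[!te])
        str_ <- sqrt(mean((yz[!te] - mtr)^2))
        if (!is.finite(str_) || str_ == 0) str_ <- 1
        m <- do.call(e1071::svm,
                     c(list(x = xm[!te, , drop = FALSE],
                            y = (yz[!te] - mtr) / str_),
                       svm_args(kern)))
        oof[te, kern] <-
          as.numeric(stats::predict(m, xm[te, , drop = FALSE])) * str_ + mtr
      }
      TRUE
    }, error = function(e) {
      warn(sprintf("SVR kernel `%s` skipped: %s", kern, conditionMessage(e)))
      FALSE
    })
    if (!ok) oof[, kern] <- NA_real_
  }
  cv_rmse <- sqrt(colMeans((oof - yz)^2))
  if (all(!is.finite(cv_rmse))) {
    abort("every SVR kernel candidate failed to train",
          class = "spectrait_model_error")
  }
  sel <- names(which.min(cv_rmse))
  model <- do.call(e1071::svm, c(list(x = xm, y = yz), svm_args(sel)))
  new_trait_model(
    "SVR", "svr_fit", features, y, coef = NULL, intercept = NULL,
    fitted = as.numeric(stats::predict(model, xm)) * ys + ym,
    oof = oof[, sel] * ys + ym,
    fold = fold,
    cv = tibble(kernel = kernels, cv_rmse = unname(cv_rmse) * ys),
    selected = list(kernel = sel, cost = cost, epsilon = epsilon,
                    gamma = gamma),
    extra = list(model = model, y_center = ym, y_scale = ys))
}

#' Predict from a fitted trait model
#'
#' Features are matched by name, so column order in `new_data` is
#' irrelevant; missing features raise a schema error. Any normalization
#' must be replayed on `new_data` beforehand with the statistics stored by
#' the preprocessing pipeline (see [apply_normalization()]).
#'
#' @param object A fitted `trait_model`.
#' @param new_data Data frame with the training feature set.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.trait_model <- function(object, new_data, ...) {
  xm <- as_feature_matrix(new_data, object$features)
  if (!is.null(object$model)) {
    as.numeric(stats::predict(object$model, xm)) * object$y_scale +
      object$y_center
  } else {
    as.numeric(xm %*% object$coefficients) + object$intercept
  }
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("<%s fit> %d features, n = %d\n", x$family,
              length(x$features), length(x$y)))
  cat("selected:", paste(names(x$selected), unlist(x$selected),
                         sep = " = ", collapse = ", "), "\n")
  g <- generics::glance(x)
  cat(sprintf("calibration R2 = %.3f, validation R2 = %.3f, RMSE(val) = %.3g\n",
              g$r2_cal, g$r2_val, g$rmse_val))
  invisible(x)
}
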