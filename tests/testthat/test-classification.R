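make_two_classes <- function(n1 = 50, n2 = 50, sep = 10, p = 5, seed = 61) {
  set.seed(seed)
  x <- as.data.frame(rbind(matrix(rnorm(n1 * p), n1),
                           cbind(matrix(rnorm(n2), n2, 1) + sep,
                                 matrix(rnorm(n2 * (p - 1)), n2))))
  names(x) <- paste0("f", 1:p)
  labels <- factor(rep(c("Class1", "Class2"), c(n1, n2)),
                   levels = c("Class1", "Class2"))
  list(x = x, labels = labels)
}

test_that("range dichotomization matches the hand-computed threshold", {
  lab <- dichotomize(1:10, fraction = 0.8)
  expect_equal(lab$threshold, 1 + 0.8 * 9)           # 8.2
  expect_equal(as.character(lab$labels),
               c(rep("Class1", 8), rep("Class2", 2)))
  # the extremes always get their class, and two values suffice
  two <- dichotomize(c(3.2, 7.9), fraction = 0.37)
  expect_equal(as.character(two$labels), c("Class1", "Class2"))
  expect_error(dichotomize(rep(4, 5)), class = "spectrait_degenerate_error")
})

test_that("labels are invariant to increasing affine transforms of the trait", {
  set.seed(62)
  v <- rnorm(200)
  base <- dichotomize(v)$labels
  expect_identical(dichotomize(3.7 * v + 11)$labels, base)
  expect_identical(dichotomize(0.01 * v - 5)$labels, base)
})

test_that("thresholds belong to the dataset: pooling regimes shifts the cut", {
  set.seed(63)
  ws <- rnorm(100, mean = 3, sd = 0.8)
  fi <- rnorm(100, mean = 9, sd = 1.1)
  t_ws <- dichotomize(ws)$threshold
  t_fi <- dichotomize(fi)$threshold
  t_pool <- dichotomize(c(ws, fi))$threshold
  expect_false(isTRUE(all.equal(t_pool, t_ws)))
  expect_false(isTRUE(all.equal(t_pool, t_fi)))
  expect_gt(t_pool, t_ws)
})

test_that("PCA-LDA separates well-separated Gaussians and not permuted labels", {
  d <- make_two_classes(sep = 10)
  fit <- fit_pca_lda(d$x, d$labels, max_pc = 5, seed = 3)
  expect_lte(glance(fit)$error_rate_val, 0.05)
  errs <- sapply(1:20, function(s) {
    set.seed(500 + s)
    perm <- sample(d$labels)
    glance(fit_pca_lda(d$x, perm, max_pc = 3, cv_folds = 5,
                       seed = 600 + s))$error_rate_val
  })
  expect_gt(mean(errs), 0.4)
  expect_lt(mean(errs), 0.6)
})

test_that("duplicating every observation leaves the LDA boundary unchanged", {
  d <- make_two_classes(n1 = 30, n2 = 30, sep = 3, seed = 64)
  # fixed component count so both fits use the same model order; the class
  # means and pooled covariance are sufficient statistics, so duplication
  # cannot move the boundary
  fit1 <- fit_pca_lda(d$x, d$labels, max_pc = 1, seed = 3)
  fit2 <- fit_pca_lda(rbind(d$x, d$x), c(d$labels, d$labels),
                      max_pc = 1, seed = 3)
  set.seed(65)
  probe <- as.data.frame(matrix(rnorm(40 * 5), 40))
  names(probe) <- names(d$x)
  expect_identical(predict(fit1, probe), predict(fit2, probe))
})

test_that("PLS-DA separates a one-factor structure and beats the prior on imbalance", {
  d <- make_two_classes(sep = 8, seed = 66)
  fit <- fit_plsda(d$x, d$labels, max_lv = 5, seed = 3)
  expect_lte(glance(fit)$error_rate_val, 0.05)
  # 80/20 imbalance with informative predictors: elite recall above the
  # 0.2 base rate of a prior-only classifier
  imb <- make_two_classes(n1 = 80, n2 = 20, sep = 3, seed = 67)
  g <- glance(fit_plsda(imb$x, imb$labels, max_lv = 5, seed = 3))
  expect_gt(g$prediction_rate_class2_val, 0.2)
})

test_that("a single-LV PLS-DA score is affine in the features", {
  d <- make_two_classes(n1 = 25, n2 = 25, sep = 4, seed = 68)
  fit <- fit_plsda(d$x, d$labels, max_lv = 1, seed = 3)
  beta <- fit$beta
  # probing: score differences are linear in coordinate displacements
  base <- as.data.frame(matrix(0, 1, 5)); names(base) <- names(d$x)
  shift <- base; shift[1, ] <- 1
  s <- function(df) as.numeric(as.matrix(df[, fit$features]) %*% beta)
  expect_equal(s(shift) - s(base), sum(beta), tolerance = 1e-12)
})

test_that("kNN predictions equal the brute-force distance-sort oracle", {
  d <- make_two_classes(n1 = 12, n2 = 8, sep = 2, seed = 69)
  fit <- fit_knn(d$x, d$labels, max_k = 5, cv_folds = 5, seed = 3)
  set.seed(70)
  queries <- as.data.frame(matrix(rnorm(20 * 5, sd = 2), 20))
  names(queries) <- names(d$x)
  ctr <- colMeans(as.matrix(d$x))
  oracle <- brute_knn(sweep(as.matrix(d$x), 2, ctr), d$labels,
                      sweep(as.matrix(queries), 2, ctr), fit$selected$k)
  expect_equal(as.character(predict(fit, queries)), oracle)
  # a query equal to a training point with k = 1 returns that point's label
  fit1 <- fit_knn(d$x, d$labels, max_k = 1, cv_folds = 5, seed = 3)
  expect_identical(as.character(predict(fit1, d$x[7, ])),
                   as.character(d$labels[7]))
})

test_that("kNN agrees with an independent implementation on tie-free instances", {
  skip_if_not_installed("class")
  d <- make_two_classes(n1 = 20, n2 = 20, sep = 1.5, seed = 71)
  set.seed(72)
  queries <- as.data.frame(matrix(rnorm(30 * 5), 30))
  names(queries) <- names(d$x)
  ctr <- colMeans(as.matrix(d$x))
  for (k in c(1, 3, 5)) {          # odd k: no vote ties possible
    mine <- spectrait:::knn_predict_matrix(
      sweep(as.matrix(d$x), 2, ctr), d$labels,
      sweep(as.matrix(queries), 2, ctr), k)
    ref <- class::knn(sweep(as.matrix(d$x), 2, ctr),
                      sweep(as.matrix(queries), 2, ctr), d$labels, k = k)
    expect_equal(mine, as.character(ref))
  }
})

test_that("kNN vote ties resolve to the nearer neighbour's label", {
  xtr <- data.frame(f = c(0, 1))
  ytr <- factor(c("Class2", "Class1"), levels = c("Class1", "Class2"))
  got <- spectrait:::knn_predict_matrix(as.matrix(xtr), ytr,
                                        matrix(0.3), k = 2)
  expect_equal(got, "Class2")       # 0 is nearer than 1
  got2 <- spectrait:::knn_predict_matrix(as.matrix(xtr), ytr,
                                         matrix(0.8), k = 2)
  expect_equal(got2, "Class1")
})

test_that("classifier predictions align features by name and reject schema gaps", {
  d <- make_two_classes(n1 = 20, n2 = 20, sep = 6, seed = 73)
  for (fitter in list(fit_pca_lda, fit_plsda, fit_knn)) {
    fit <- fitter(d$x, d$labels, seed = 3)
    expect_identical(predict(fit, d$x), fit$fitted)
    expect_identical(predict(fit, rev(d$x)), fit$fitted)
    expect_error(predict(fit, d$x[-2]), class = "spectrait_schema_error")
  }
})

test_that("classifiers beat the majority baseline on separable data only", {
  d <- make_two_classes(n1 = 60, n2 = 15, sep = 6, seed = 74)
  fits <- list(fit_pca_lda(d$x, d$labels, max_pc = 5, seed = 3),
               fit_plsda(d$x, d$labels, max_lv = 5, seed = 3),
               fit_knn(d$x, d$labels, max_k = 5, seed = 3))
  for (fit in fits) {
    # the majority baseline has macro error 0.5 (zero elite recall)
    expect_lt(glance(fit)$error_rate_val, 0.35)
  }
})
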