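# Shared fixtures and independent oracles for the suite. The benchmark
# scene is generated once per run and reused.

.fixture_cache <- new.env(parent = emptyenv())

# 16-genotype scene (128 spectra): the default unit-test scene.
scene16 <- function() {
  if (is.null(.fixture_cache$s16)) {
    .fixture_cache$s16 <- make_benchmark_fixture(seed = 42, n_genotypes = 16)
  }
  .fixture_cache$s16
}

# One aligned, preprocessed regression dataset from the scene (GY at GF,
# pooled environments), cached.
scene16_gy <- function() {
  if (is.null(.fixture_cache$gy16)) {
    fx <- scene16()
    sp <- trim_noise_bands(fx$spectra)
    al <- align_observations(sp, fx$traits, "GY", "m",
                             stage = "GF", environment = "WS+FI")
    pp <- preprocess(al[band_cols(al)], al$trait_value, lof_k = 10)
    .fixture_cache$gy16 <- pp
  }
  .fixture_cache$gy16
}

# Small wide spectra table built by hand.
toy_spectra <- function(values, wl = NULL, ids = NULL) {
  values <- as.matrix(values)
  if (is.null(wl)) wl <- seq(350, length.out = ncol(values))
  if (is.null(ids)) ids <- paste0("obs", seq_len(nrow(values)))
  colnames(values) <- as.character(wl)
  dplyr::bind_cols(tibble::tibble(observation_id = ids),
                   tibble::as_tibble(as.data.frame(values,
                                                   check.names = FALSE)))
}

# Brute-force LOF straight from the definition, kept independent of the
# package implementation (explicit loops, no shared helpers).
brute_lof <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  kdist <- numeric(n)
  nb <- vector("list", n)
  for (i in 1:n) {
    srt <- sort(d[i, ])
    kdist[i] <- srt[k]
    nb[[i]] <- which(d[i, ] <= kdist[i])
  }
  lrd <- sapply(1:n, function(i) {
    rd <- sapply(nb[[i]], function(o) max(kdist[o], d[i, o]))
    if (mean(rd) == 0) Inf else 1 / mean(rd)
  })
  sapply(1:n, function(i) {
    ratio <- lrd[nb[[i]]] / lrd[i]
    ratio[is.nan(ratio)] <- 1
    mean(ratio)
  })
}

# OLS predictions oracle (QR through lm.fit).
ols_predictions <- function(x, y, newx = x) {
  x <- as.matrix(x); newx <- as.matrix(newx)
  fit <- lm.fit(cbind(1, x), y)
  as.numeric(cbind(1, newx) %*% fit$coefficients)
}

# Brute-force kNN oracle: full distance sort, majority vote, vote ties to
# the nearest neighbour, distance ties by training order.
brute_knn <- function(xtr, ytr, xte, k) {
  xtr <- as.matrix(xtr); xte <- as.matrix(xte)
  ytr <- as.character(ytr)
  out <- character(nrow(xte))
  for (i in seq_len(nrow(xte))) {
    d <- sqrt(rowSums((xtr - matrix(xte[i, ], nrow(xtr), ncol(xtr),
                                    byrow = TRUE))^2))
    nn <- order(d)[1:k]
    tab <- table(factor(ytr[nn], levels = c("Class1", "Class2")))
    out[i] <- if (tab[1] == tab[2]) ytr[nn[1]] else names(which.max(tab))
  }
  out
}
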