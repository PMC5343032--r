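# Pre-modelling hygiene: drop incomplete rows, screen multivariate outliers
# with the Local Outlier Factor, and normalize columns with statistics that
# can be replayed on held-out folds (no leakage).

#' Drop observations with missing predictors or response
#'
#' @param x Predictor table (data frame or matrix), rows keyed to `y`.
#' @param y Response vector of length `nrow(x)`, or `NULL`.
#' @return A list with `x`, `y` (rows with any `NA` removed) and `kept`, a
#'   logical vector over the input rows.
#' @export
drop_missing <- function(x, y = NULL) {
  x <- as.data.frame(x)
  keep <- stats::complete.cases(x)
  if (!is.null(y)) {
    stopifnot(length(y) == nrow(x))
    keep <- keep & !is.na(y)
  }
  if (!any(keep)) {
    abort("all observations removed by missing-value exclusion",
          class = "spectrait_empty_error")
  }
  list(x = x[keep, , drop = FALSE],
       y = if (is.null(y)) NULL else y[keep],
       kept = keep)
}

#' Local Outlier Factor scores
#'
#' Standard density-ratio LOF (Breunig et al.): for each point, the
#' k-distance neighbourhood (including distance ties), reachability
#' distances `max(k_dist(o), d(p, o))`, local reachability density as the
#' inverse mean reachability distance, and the score as the mean ratio of
#' neighbour densities to the point's own. Scores near 1 indicate points in
#' regions of homogeneous density; scores well above 1 indicate isolation.
#' Duplicate-heavy data are handled by the usual convention that infinite
#' densities cancel (ratio 1), so no division by zero occurs.
#'
#' @param x Numeric table or matrix (rows = observations). Euclidean metric;
#'   normalize columns first if their scales differ.
#' @param n_neighbors Neighbourhood size `k` (default 20, the method's
#'   common default); must be `< nrow(x)`.
#' @return Numeric vector of LOF scores, one per row.
#' @export
lof_scores <- function(x, n_neighbors = 20) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- as.integer(n_neighbors)
  if (k < 1L || k >= n) {
    abort("`n_neighbors` must satisfy 1 <= k < nrow(x)",
          class = "spectrait_parameter_error")
  }
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  neigh <- vector("list", n)
  k_dist <- numeric(n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    kd <- sort(di, partial = k)[k]
    k_dist[i] <- kd
    neigh[[i]] <- which(di <= kd)   # includes ties at the k-distance
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    reach <- pmax(k_dist[neigh[[i]]], d[i, neigh[[i]]])
    m <- mean(reach)
    lrd[i] <- if (m == 0) Inf else 1 / m
  }
  score <- numeric(n)
  for (i in seq_len(n)) {
    r <- lrd[neigh[[i]]] / lrd[i]
    r[is.nan(r)] <- 1          # Inf/Inf: duplicated points share density
    score[i] <- mean(r)
  }
  score
}

#' Column normalization with replayable statistics
#'
#' `normalize()` estimates per-column statistics and transforms the data;
#' `apply_normalization()` replays stored statistics on new rows, which is
#' how validation folds are transformed without leaking their values into
#' the training statistics.
#'
#' @param x Numeric table (data frame or matrix).
#' @param mode `"zscore"` (centre and divide by the sample, n-1, standard
#'   deviation; zero-variance columns are centred only), `"mean_center"`,
#'   or `"none"`.
#' @return A list with `x` (transformed tibble) and `stats`, a tibble of
#'   `column`, `center`, `scale` accepted by `apply_normalization()`.
#' @export
#' @examples
#' normalize(data.frame(a = 1:3), "zscore")$x
normalize <- function(x, mode = c("zscore", "mean_center", "none")) {
  mode <- match.arg(mode)
  x <- as.data.frame(x)
  ctr <- vapply(x, mean, numeric(1))
  scl <- rep(1, ncol(x))
  if (mode == "none") ctr <- rep(0, ncol(x))
  if (mode == "zscore") {
    scl <- vapply(x, stats::sd, numeric(1))
    scl[!is.finite(scl) | scl == 0] <- 1
  }
  stats <- tibble(column = names(x), center = ctr, scale = scl, mode = mode)
  list(x = apply_normalization(x, stats), stats = stats)
}

#' @rdname normalize
#' @param stats Statistics tibble returned by `normalize()`.
#' @export
apply_normalization <- function(x, stats) {
  x <- as.data.frame(x)
  miss <- setdiff(stats$column, names(x))
  if (length(miss) > 0L) {
    abort(sprintf("new data is missing column(s): %s",
                  paste(utils::head(miss, 5), collapse = ", ")),
          class = "spectrait_schema_error")
  }
  x <- x[stats$column]
  out <- sweep(sweep(as.matrix(x), 2L, stats$center, "-"), 2L, stats$scale, "/")
  as_tibble(as.data.frame(out, check.names = FALSE))
}

#' Canonical preprocessing pipeline
#'
#' Missing-value exclusion, then LOF outlier screening, then normalization,
#' in that order. The returned report accounts for every input row
#' (`n_input = n_missing_dropped + n_outliers_dropped + n_retained`) and the
#' stored statistics suffice to transform new data identically.
#'
#' @param x Predictor table.
#' @param y Optional response vector.
#' @param mode Normalization mode; regression pipelines use `"zscore"`,
#'   classification pipelines `"mean_center"`.
#' @param lof_k LOF neighbourhood size (default 20); set `lof_k = 0` to skip
#'   outlier screening.
#' @param lof_cutoff Observations with LOF score above this are dropped
#'   (default 1.5).
#' @return A list with `x` (transformed), `y`, `stats` and `report` (a
#'   one-row tibble of counts plus the per-retained-row `lof` scores as an
#'   attribute-free list column).
#' @export
preprocess <- function(x, y = NULL, mode = "zscore", lof_k = 20,
                       lof_cutoff = 1.5) {
  n_input <- nrow(as.data.frame(x))
  dm <- drop_missing(x, y)
  n_missing <- n_input - nrow(dm$x)
  x2 <- dm$x; y2 <- dm$y
  lof <- rep(NA_real_, nrow(x2))
  n_out <- 0L
  if (lof_k >= 1 && lof_k < nrow(x2)) {
    z <- normalize(x2, "zscore")$x
    lof <- lof_scores(z, n_neighbors = lof_k)
    keep <- lof <= lof_cutoff
    n_out <- sum(!keep)
    if (!any(keep)) {
      abort("LOF screening removed every observation",
            class = "spectrait_empty_error")
    }
    x2 <- x2[keep, , drop = FALSE]
    if (!is.null(y2)) y2 <- y2[keep]
    lof <- lof[keep]
  }
  nm <- normalize(x2, mode)
  report <- tibble(
    n_input = n_input, n_missing_dropped = n_missing,
    n_outliers_dropped = n_out, n_retained = nrow(x2),
    normalization = mode, lof_k = lof_k, lof_cutoff = lof_cutoff,
    lof_scores = list(lof), order = "drop_missing > lof > normalize")
  list(x = nm$x, y = y2, stats = nm$stats, report = report)
}
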