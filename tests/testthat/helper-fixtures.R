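# Shared fixtures and independent oracles for the test suite.

# memoized small landscape so several files can reuse one generation
.fixture_env <- new.env(parent = emptyenv())

small_landscape <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- generate_landscape(landscape_config(
      grid_rows = 30, grid_cols = 30, n_counties = 8, n_years = 2, seed = 7))
  }
  .fixture_env$small
}

default_landscape <- function() {
  if (is.null(.fixture_env$default)) {
    .fixture_env$default <- generate_landscape(landscape_config())
  }
  .fixture_env$default
}

# Brute-force Mahalanobis oracle: explicit covariance inverse, per-pixel loop.
oracle_mahalanobis <- function(D) {
  u <- colMeans(D)
  cov_inv <- solve(stats::cov(D))
  apply(D, 1L, function(d) sqrt(t(d - u) %*% cov_inv %*% (d - u)))
}

# Term-by-term Davies-Bouldin oracle on 1-D data.
oracle_dbi <- function(values, labels) {
  ids <- sort(unique(labels))
  k <- length(ids)
  total <- 0
  for (x in ids) {
    vx <- values[labels == x]
    best <- -Inf
    for (y in setdiff(ids, x)) {
      vy <- values[labels == y]
      ax <- mean(abs(vx - mean(vx)))
      ay <- mean(abs(vy - mean(vy)))
      sep <- abs(mean(vx) - mean(vy))
      r <- if (sep == 0) Inf else (ax + ay) / sep
      if (r > best) best <- r
    }
    total <- total + best
  }
  total / k
}

# Recoverable-by-construction log-linear feature table: response is an exact
# exp-linear function of the features, so log1p(response) is linear.
loglinear_table <- function(n, n_features = 2L, seed = 7L,
                            coefs = c(2, 0.9, 0.3)) {
  set.seed(seed)
  tbl <- data.frame(county_id = 1L, group_id = seq_len(n), n_pixels = 1L,
                    response = NA_real_, grassland_type = 1L)
  lin <- rep(coefs[1L], n)
  for (j in seq_len(n_features)) {
    f <- stats::runif(n, -1, 1)
    tbl[[paste0("f", j)]] <- f
    lin <- lin + coefs[j + 1L] * f
  }
  tbl$response <- expm1(lin)
  class(tbl) <- c("group_feature_table", "data.frame")
  tbl
}
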