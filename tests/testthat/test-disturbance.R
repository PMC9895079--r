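test_that("identical deviation vectors give zero disturbance everywhere", {
  obs <- list(matrix(0.5, 3, 3), matrix(0.4, 3, 3))
  pot <- list(matrix(0.6, 3, 3), matrix(0.7, 3, 3))
  out <- ad_index(obs, pot)
  expect_true(all(out$ad == 0))
  expect_identical(out$lambda, 0)
})

test_that("a whitened toy reduces Mahalanobis to the Euclidean norm", {
  # four deviation vectors whose sample covariance is exactly the identity
  s <- sqrt(3) / 2
  D <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)) * s
  obs <- list(matrix(D[, 1], 2, 2), matrix(D[, 2], 2, 2))
  pot <- list(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(stats::cov(D), diag(2), tolerance = 1e-12)
  out <- ad_index(obs, pot)
  expect_equal(as.vector(out$ad), sqrt(rowSums(D^2)), tolerance = 1e-12)
})

test_that("the index matches a dense-algebra oracle on a 5-pixel toy", {
  set.seed(2)
  D <- matrix(stats::rnorm(15), 5, 3)
  obs <- lapply(1:3, function(t) matrix(D[, t], 5, 1))
  pot <- lapply(1:3, function(t) matrix(0, 5, 1))
  out <- ad_index(obs, pot)
  expect_equal(as.vector(out$ad), unname(oracle_mahalanobis(D)),
               tolerance = 1e-10)
})

test_that("the index matches the oracle on instances up to 100 pixels, T <= 12", {
  set.seed(3)
  for (case in 1:5) {
    n <- sample(10:100, 1)
    T_len <- sample(1:12, 1)
    D <- matrix(stats::rnorm(n * T_len, sd = 0.1), n, T_len)
    obs <- lapply(seq_len(T_len), function(t) matrix(D[, t], n, 1))
    pot <- lapply(seq_len(T_len), function(t) matrix(0, n, 1))
    out <- ad_index(obs, pot)
    expect_equal(as.vector(out$ad), unname(oracle_mahalanobis(D)),
                 tolerance = 1e-8)
  }
})

test_that("a pixel-independent shift of all deviations leaves AD unchanged", {
  set.seed(4)
  D <- matrix(stats::rnorm(24), 8, 3)
  shift <- c(5, -2, 0.3)
  mk <- function(M) lapply(1:3, function(t) matrix(M[, t], 8, 1))
  base <- ad_index(mk(D), mk(matrix(0, 8, 3)))
  shifted <- ad_index(mk(sweep(D, 2, -shift)), mk(matrix(0, 8, 3)))
  expect_equal(shifted$ad, base$ad, tolerance = 1e-10)
})

test_that("singular covariances are ridge-regularized and reported", {
  # two perfectly collinear time steps
  set.seed(5)
  d1 <- stats::rnorm(6)
  obs <- list(matrix(d1, 3, 2), matrix(2 * d1, 3, 2))
  pot <- list(matrix(0, 3, 2), matrix(0, 3, 2))
  out <- ad_index(obs, pot)
  expect_gt(out$lambda, 0)
  expect_true(all(is.finite(out$ad)))
})

test_that("degenerate NDVI inputs are rejected", {
  expect_error(ad_index(list(), list()), "no time steps")
  expect_error(ad_index(matrix(1, 1, 1), matrix(0, 1, 1)), "2 valid pixels")
})

test_that("distribution is proportional to the AD weight", {
  zones <- matrix(1L, 1, 2)
  cen <- census_table(data.frame(county_id = 1, year = 1, su_total = 100))
  out <- dasymetric_distribute(cen, matrix(c(1, 3), 1, 2), zones)
  expect_equal(as.vector(out$su), c(25, 75))
})

test_that("equal weights split uniformly; zero weights fall back uniformly", {
  zones <- matrix(1L, 2, 2)
  cen <- census_table(data.frame(county_id = 1, year = 1, su_total = 100))
  equal <- dasymetric_distribute(cen, matrix(2, 2, 2), zones)
  expect_equal(as.vector(equal$su), rep(25, 4))
  zero <- dasymetric_distribute(cen, matrix(0, 2, 2), zones)
  expect_equal(as.vector(zero$su), rep(25, 4))
  expect_equal(zero$uniform_counties, 1)
})

test_that("zonal sums reproduce the census on a full landscape", {
  truth <- small_landscape()
  mask <- !is.na(truth$county_zones)
  ad <- ad_index(truth$ndvi_observed, truth$ndvi_potential, valid_mask = mask)
  cen <- census_table(as.data.frame(
    truth$census[truth$census$year == 1, , drop = FALSE]))
  dist <- dasymetric_distribute(cen, ad, truth$county_zones, mask, year = 1)
  sums <- zonal_sum(dist$su, truth$county_zones)
  expect_lt(max(abs(as.numeric(sums[as.character(cen$county_id)]) -
                      cen$su_total) / pmax(cen$su_total, 1)), 1e-9)
  expect_true(all(dist$su[!is.na(dist$su)] >= 0))
})

test_that("counties without suitable pixels are reported, not fatal", {
  zones <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  cen <- census_table(data.frame(county_id = c(1, 2), year = 1,
                                 su_total = c(10, 5)))
  out <- dasymetric_distribute(cen, matrix(1, 2, 2), zones, mask)
  expect_equal(out$undistributable$county_id, 2)
  expect_equal(out$undistributable$su_total, 5)
  expect_equal(sum(out$su, na.rm = TRUE), 10)
})
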