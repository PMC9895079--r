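test_that("the carrying-capacity threshold follows the forage balance", {
  expect_equal(capacity_threshold(1000, 0.5, 1.8, 365), 0.761, tolerance = 1e-3)
  expect_equal(capacity_threshold(2000, 1, 1.8, 365),
               2 * capacity_threshold(1000, 1, 1.8, 365))
  expect_error(capacity_threshold(-1, 0.5, 1.8, 365), "> 0")
  expect_error(capacity_threshold(1000, 1.5, 1.8, 365), "utilization")
})

test_that("samples split at the per-type threshold with boundary going low", {
  spec <- default_partition_spec(pixel_area_hm2 = 100)
  tbl <- data.frame(
    county_id = 1:3, group_id = 1L, n_pixels = 1L,
    response = c(0.43, 0.50, 0.30) * 100,          # SU/pixel at 100 hm2
    grassland_type = c(1L, 1L, 2L),                # meadow, meadow, steppe
    f1 = 0)
  parts <- partition_samples(tbl, spec)
  expect_setequal(parts$low$county_id, c(1, 3))    # boundary meadow -> low
  expect_identical(parts$high$county_id, 2L)
  expect_error(partition_samples(transform(tbl, grassland_type = 9L), spec),
               "unknown grassland type")
})

test_that("a noise-free log-linear table is recovered with high accuracy", {
  tbl <- loglinear_table(1200, n_features = 2, seed = 7)
  m <- fit_spatializer(tbl, "M1", split_seed = 11, model_seed = 12)
  expect_gte(m$holdout$pooled$r2, 0.99)
  expect_identical(m$response_transform$family, "natural-log")
})

test_that("refitting with identical seeds is bit-identical", {
  tbl <- loglinear_table(120, n_features = 2, seed = 3)
  a <- fit_spatializer(tbl, "M1", split_seed = 5, model_seed = 6,
                       num_trees = 100)
  b <- fit_spatializer(tbl, "M1", split_seed = 5, model_seed = 6,
                       num_trees = 100)
  expect_identical(a$importances, b$importances)
  expect_identical(a$holdout, b$holdout)
  covs <- list(f1 = matrix(stats::runif(25, -1, 1), 5, 5),
               f2 = matrix(stats::runif(25, -1, 1), 5, 5))
  gt <- matrix(1L, 5, 5)
  expect_identical(predict(a, covs, gt), predict(b, covs, gt))
})

test_that("an empty partition falls back to a single model with a warning", {
  tbl <- loglinear_table(40, n_features = 2, seed = 4)
  tbl$response <- tbl$response / 1e6      # everything far below threshold
  expect_warning(m <- fit_spatializer(tbl, "M4", num_trees = 100),
                 "falling back")
  expect_true(m$partition_fallback)
  expect_named(m$submodels, "pooled")
})

test_that("prediction routes pixels and honors the mask", {
  tbl <- loglinear_table(200, n_features = 2, seed = 5)
  tbl$response <- tbl$response * 10   # densities straddle the thresholds
  tbl$grassland_type <- rep(1:2, length.out = 200)
  m <- fit_spatializer(tbl, "M4", num_trees = 100)
  covs <- list(f1 = matrix(stats::runif(36, -1, 1), 6, 6),
               f2 = matrix(stats::runif(36, -1, 1), 6, 6))
  gt <- matrix(rep(1:2, 18), 6, 6)
  mask <- matrix(TRUE, 6, 6); mask[1, ] <- FALSE
  pred <- predict(m, covs, gt, mask)
  expect_true(all(is.na(pred[1, ])))
  expect_true(all(pred[-1, ] >= 0))
  # all-false mask -> all-nodata output
  expect_true(all(is.na(predict(m, covs, gt, mask = matrix(FALSE, 6, 6)))))
  # constant covariates -> constant prediction on the mask
  const <- list(f1 = matrix(0.3, 6, 6), f2 = matrix(-0.1, 6, 6))
  pc <- predict(m, const, gt, mask)
  expect_lt(diff(range(pc[!is.na(pc) & gt == 1])), 1e-12)
  expect_error(predict(m, covs[1], gt), "missing feature")
})

test_that("a noise-free fixture predicts within 5% of truth on 95% of pixels", {
  tbl <- loglinear_table(1200, n_features = 1, seed = 7, coefs = c(2, 0.9))
  m <- fit_spatializer(tbl, "M1", split_seed = 11, model_seed = 12)
  set.seed(8)
  f1 <- matrix(stats::runif(900, -1, 1), 30, 30)
  truth <- expm1(2 + 0.9 * f1)
  pred <- predict(m, list(f1 = f1), matrix(1L, 30, 30))
  rel <- abs(pred - truth) / truth
  expect_gte(mean(rel <= 0.05), 0.95)
})

test_that("residual correction shifts county means onto the census", {
  zones <- matrix(1L, 2, 2)
  raw <- matrix(c(4, 5, 5, 6), 2, 2)       # county mean 5
  cen <- census_table(data.frame(county_id = 1, year = 1, su_total = 28))
  out <- residual_correct(raw, cen, zones)  # census mean 7
  expect_equal(out$su_corrected, raw + 2)
  expect_equal(mean(out$su_corrected), 7)
})

test_that("an already-consistent grid is returned unchanged", {
  zones <- matrix(1L, 2, 2)
  raw <- matrix(c(4, 6, 8, 10), 2, 2)
  cen <- census_table(data.frame(county_id = 1, year = 1,
                                 su_total = sum(raw)))
  out <- residual_correct(raw, cen, zones)
  expect_equal(out$su_corrected, raw)
})

test_that("clipped negatives are re-spread, keeping mass and nonnegativity", {
  zones <- matrix(1L, 1, 5)
  raw <- matrix(c(0.5, 1, 2, 8, 30), 1, 5)
  cen <- census_table(data.frame(county_id = 1, year = 1, su_total = 15))
  out <- residual_correct(raw, cen, zones, tol = 1e-9)
  x <- as.vector(out$su_corrected)
  expect_true(all(x >= 0))
  expect_equal(sum(x), 15, tolerance = 1e-6)
  # independent oracle: additive shift, then iterative clip-and-rescale
  y <- as.vector(raw) + (15 / 5 - mean(raw))
  for (i in 1:100) {
    if (all(y >= 0)) break
    y <- pmax(y, 0)
    y <- y * 15 / sum(y)
  }
  expect_equal(x, y, tolerance = 1e-9)
})

test_that("counties missing from the census stay uncorrected and reported", {
  zones <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  raw <- matrix(1, 2, 2)
  cen <- census_table(data.frame(county_id = 1, year = 1, su_total = 10))
  out <- residual_correct(raw, cen, zones)
  expect_identical(out$uncorrected_counties, 2L)
  expect_equal(out$su_corrected[zones == 2L], raw[zones == 2L])
  expect_equal(sum(out$su_corrected[zones == 1L]), 10)
})
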