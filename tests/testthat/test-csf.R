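test_that("zero within-group spread gives a zero Davies-Bouldin index", {
  expect_equal(davies_bouldin(c(0, 0, 10, 10), c(1, 1, 2, 2)), 0)
})

test_that("coincident centroids flag the grouping as degenerate", {
  expect_identical(davies_bouldin(c(0, 2, 0, 2), c(1, 1, 2, 2)), Inf)
})

test_that("a 9-point three-group toy matches the term-by-term oracle", {
  values <- c(1, 2, 3, 10, 11, 12, 25, 28, 31)
  labels <- rep(1:3, each = 3)
  expect_equal(davies_bouldin(values, labels),
               oracle_dbi(values, labels), tolerance = 1e-12)
})

test_that("the index matches the oracle on random groupings", {
  set.seed(8)
  for (i in 1:10) {
    n <- sample(6:30, 1)
    k <- sample(2:4, 1)
    values <- stats::rnorm(n)
    labels <- sample(rep(seq_len(k), length.out = n))
    expect_equal(davies_bouldin(values, labels),
                 oracle_dbi(values, labels), tolerance = 1e-10)
  }
})

test_that("grouping everything together is an error", {
  expect_error(davies_bouldin(1:5, rep(1, 5)), "at least 2 groups")
})

test_that("well-separated clumps select their true count", {
  set.seed(9)
  values <- c(stats::rnorm(20, 0, 0.5), stats::rnorm(20, 50, 0.5),
              stats::rnorm(20, 100, 0.5))
  sel <- select_group_count(values, k_range = 2:6)
  expect_identical(sel$k_selected, 3L)
  expect_identical(sel$k_candidates, 2:6)
  expect_equal(which.min(sel$dbi_values), 2L)
})

test_that("structureless or tiny inputs collapse to one group", {
  expect_identical(select_group_count(rep(3.2, 10))$k_selected, 1L)
  expect_identical(select_group_count(numeric(0))$k_selected, 1L)
  expect_identical(select_group_count(5)$k_selected, 1L)
  expect_identical(select_group_count(1:10, k_range = 1L)$k_selected, 1L)
})

test_that("selection is deterministic", {
  set.seed(10)
  values <- stats::rnorm(40)
  a <- select_group_count(values)
  b <- select_group_count(values)
  expect_identical(a, b)
})

test_that("a homogeneous county collapses to its county-mean row", {
  zones <- matrix(1L, 2, 2)
  su <- matrix(4, 2, 2)
  covs <- list(cov1 = matrix(c(1, 2, 3, 4), 2, 2))
  gt <- matrix(1L, 2, 2)
  out <- extract_csf(su, covs, zones, gt)
  expect_identical(nrow(out), 1L)
  expect_equal(out$response, 4)
  expect_equal(out$cov1, 2.5)
  expect_identical(out$n_pixels, 4L)
})

test_that("a bimodal toy county splits into its two groups", {
  zones <- matrix(1L, 2, 2)
  su <- matrix(c(1, 1, 9, 9), 2, 2)
  covs <- list(cov1 = matrix(c(2, 2, 4, 4), 2, 2))
  gt <- matrix(1L, 2, 2)
  out <- extract_csf(su, covs, zones, gt)
  out <- out[order(out$response), ]
  expect_equal(out$response, c(1, 9))
  expect_equal(out$cov1, c(2, 4))
  expect_equal(out$n_pixels, c(2L, 2L))
})

test_that("groups partition each county and aggregate consistently", {
  truth <- small_landscape()
  mask <- !is.na(truth$county_zones)
  ad <- ad_index(truth$ndvi_observed, truth$ndvi_potential, valid_mask = mask)
  cen <- census_table(as.data.frame(
    truth$census[truth$census$year == 1, , drop = FALSE]))
  dist <- dasymetric_distribute(cen, ad, truth$county_zones, mask, year = 1)
  tbl <- extract_csf(dist, truth$covariates, truth$county_zones,
                     truth$grassland_type)
  for (cid in unique(tbl$county_id)) {
    rows <- tbl[tbl$county_id == cid, ]
    idx <- which(truth$county_zones == cid & !is.na(dist$su))
    expect_identical(sum(rows$n_pixels), length(idx))           # partition
    expect_equal(sum(rows$n_pixels * rows$response), sum(dist$su[idx]),
                 tolerance = 1e-9)                              # aggregation
  }
  # group-level table strictly enlarges the training sample
  expect_gt(nrow(tbl), length(unique(tbl$county_id)))
})

test_that("the county-mean table is the k = 1 special case", {
  truth <- small_landscape()
  mask <- !is.na(truth$county_zones)
  ad <- ad_index(truth$ndvi_observed, truth$ndvi_potential, valid_mask = mask)
  cen <- census_table(as.data.frame(
    truth$census[truth$census$year == 1, , drop = FALSE]))
  dist <- dasymetric_distribute(cen, ad, truth$county_zones, mask, year = 1)
  tbl <- county_feature_table(dist, truth$covariates, truth$county_zones,
                              truth$grassland_type)
  expect_identical(nrow(tbl), truth$config$n_counties)
  expect_true(all(tbl$group_id == 1L))
  # county mean density equals census total / pixel count
  cid <- tbl$county_id[1]
  n <- sum(truth$county_zones == cid)
  expect_equal(tbl$response[1],
               cen$su_total[cen$county_id == cid] / n, tolerance = 1e-9)
})
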