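#' Absolute disturbance (AD) index from NDVI time series
#'
#' For each pixel, the deviation vector `D_i` between observed and potential
#' NDVI over T time steps is scored by its Mahalanobis distance from the
#' study-area mean deviation:
#' `AD_i = sqrt((D_i - u)' cov^{-1} (D_i - u))`, with `u` and `cov` the mean
#' and T-by-T covariance of the deviations over all valid pixels. Larger AD
#' means the pixel's NDVI trajectory departs further from the undisturbed
#' norm — the proxy for grazing pressure used as the dasymetric weight.
#'
#' The pixel population for `u` and `cov` is global (all valid masked
#' pixels), giving a common disturbance scale across counties. A numerically
#' singular covariance is ridge-regularized with `lambda = 1e-8 tr(cov)/T`
#' (always reported); if every pixel shares one deviation vector the index
#' is identically zero without any inversion.
#'
#' @param observed,potential NDVI stacks: lists of matrices (one per time
#'   step) or single matrices for T = 1, on a shared lattice, values in
#'   [-1, 1].
#' @param valid_mask optional logical matrix; pixels outside it, or with any
#'   missing NDVI step, are excluded from the statistics and get `NA` AD.
#' @return object of class `ad_field`: list with `ad` (matrix, >= 0 on valid
#'   pixels), `lambda` (ridge used, 0 if none), `cov_condition` (condition
#'   number of the covariance), `n_valid`.
#' @examples
#' obs <- list(matrix(c(0.2, 0.4, 0.3, 0.5), 2, 2))
#' pot <- list(matrix(0.6, 2, 2))
#' ad_index(obs, pot)$ad
#' @export
ad_index <- function(observed, potential, valid_mask = NULL) {
  if (is.matrix(observed)) observed <- list(observed)
  if (is.matrix(potential)) potential <- list(potential)
  T_len <- length(observed)
  if (T_len == 0L) stop("NDVI series has no time steps")
  if (length(potential) != T_len)
    stop("observed and potential stacks differ in length")
  do.call(check_same_lattice, c(observed, potential,
                                if (!is.null(valid_mask)) list(valid_mask)))
  dims <- dim(observed[[1L]])

  D <- vapply(seq_len(T_len),
              function(t) as.vector(observed[[t]] - potential[[t]]),
              numeric(prod(dims)))
  D <- matrix(D, ncol = T_len)
  valid <- stats::complete.cases(D)
  if (!is.null(valid_mask)) valid <- valid & as.vector(valid_mask) %in% TRUE
  n_valid <- sum(valid)
  if (n_valid < 2L) stop("need at least 2 valid pixels")

  Dv <- D[valid, , drop = FALSE]
  ad <- matrix(NA_real_, dims[1L], dims[2L])

  # degenerate: every pixel shares one deviation vector -> AD = 0, no inversion
  if (all(abs(sweep(Dv, 2L, Dv[1L, ])) < 1e-12)) {
    ad[valid] <- 0
    return(structure(list(ad = ad, lambda = 0, cov_condition = NA_real_,
                          n_valid = n_valid),
                     class = "ad_field"))
  }

  u <- colMeans(Dv)
  covm <- stats::cov(Dv)
  cond <- kappa(covm, exact = TRUE)
  lambda <- 0
  R <- tryCatch(chol(covm), error = function(e) NULL)
  if (is.null(R) || !is.finite(cond) || cond > 1e12) {
    lambda <- 1e-8 * sum(diag(covm)) / T_len
    if (lambda <= 0) lambda <- 1e-12
    R <- chol(covm + diag(lambda, T_len))
  }
  Dc <- sweep(Dv, 2L, u)
  z <- backsolve(R, t(Dc), transpose = TRUE)
  ad[valid] <- sqrt(colSums(z^2))
  structure(list(ad = ad, lambda = lambda, cov_condition = cond,
                 n_valid = n_valid),
            class = "ad_field")
}

#' @export
print.ad_field <- function(x, ...) {
  cat(sprintf("AD index field: %d valid pixels, range [%.3g, %.3g]\n",
              x$n_valid, min(x$ad, na.rm = TRUE), max(x$ad, na.rm = TRUE)))
  if (x$lambda > 0)
    cat(sprintf("  ridge regularization lambda = %.3g\n", x$lambda))
  invisible(x)
}

#' Dasymetrically distribute county census totals by AD weight
#'
#' Each county's census SU total is split over its suitable pixels in
#' proportion to the AD index: `SU_i = SU_j^C * AD_i / sum_j(AD)`. Zonal
#' sums therefore reproduce the census by construction. A county whose AD
#' weights sum to zero falls back to a uniform split (reported); a county
#' with census > 0 but no suitable pixel cannot receive its total and is
#' listed as undistributable rather than aborting the run.
#'
#' @param census a [census_table()]; rows for `year` are used.
#' @param ad an [ad_index()] result or a bare AD matrix.
#' @param zones integer county-label raster field.
#' @param mask logical matrix or [build_suitability_mask()] result; defaults
#'   to all pixels with a county label.
#' @param year which census year to distribute (default: the single year
#'   present, an error if several).
#' @return object of class `distributed_density`: list with `su` (matrix,
#'   SU/pixel, `NA` off-mask), `year`, `uniform_counties` (ids that used the
#'   uniform fallback), `undistributable` (data.frame of dropped counties
#'   and their census totals).
#' @examples
#' zones <- matrix(1L, 1, 2)
#' adm <- matrix(c(1, 3), 1, 2)
#' cen <- census_table(data.frame(county_id = 1, year = 1, su_total = 100))
#' dasymetric_distribute(cen, adm, zones)$su  # 25, 75
#' @export
dasymetric_distribute <- function(census, ad, zones, mask = NULL, year = NULL) {
  stopifnot(inherits(census, "census_table"))
  adm <- if (inherits(ad, "ad_field")) ad$ad else ad
  if (inherits(mask, "suitability_mask")) mask <- mask$mask
  if (is.null(mask)) mask <- !is.na(zones)
  check_same_lattice(adm, zones, mask)
  if (is.null(year)) {
    yrs <- unique(census$year)
    if (length(yrs) != 1L)
      stop("census covers several years; pass `year`")
    year <- yrs
  }
  rows <- census[census$year == year, , drop = FALSE]
  if (nrow(rows) == 0L) stop("census has no rows for year ", year)

  su <- matrix(NA_real_, nrow(adm), ncol(adm))
  uniform <- integer(0)
  undist <- list()
  usable <- mask & !is.na(zones) & !is.na(adm)
  for (k in seq_len(nrow(rows))) {
    cid <- rows$county_id[k]
    total <- rows$su_total[k]
    idx <- which(usable & zones == cid)
    if (length(idx) == 0L) {
      if (total > 0)
        undist[[length(undist) + 1L]] <- data.frame(county_id = cid,
                                                    su_total = total)
      next
    }
    w <- adm[idx]
    s <- sum(w)
    if (s <= 0) {
      su[idx] <- total / length(idx)
      uniform <- c(uniform, cid)
    } else {
      su[idx] <- total * w / s
    }
  }
  structure(
    list(su = su, year = year, uniform_counties = uniform,
         undistributable = if (length(undist)) do.call(rbind, undist)
                           else data.frame(county_id = integer(0),
                                           su_total = numeric(0))),
    class = "distributed_density"
  )
}

#' @export
print.distributed_density <- function(x, ...) {
  cat(sprintf("Distributed grazing density, year %s: %d pixels, %.1f SU\n",
              format(x$year), sum(!is.na(x$su)), sum(x$su, na.rm = TRUE)))
  if (length(x$uniform_counties))
    cat("  uniform fallback in counties:",
        paste(x$uniform_counties, collapse = ", "), "\n")
  if (nrow(x$undistributable))
    cat("  undistributable counties:",
        paste(x$undistributable$county_id, collapse = ", "), "\n")
  invisible(x)
}
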