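#' Spatial agreement metrics: R2, RMSE, MAE
#'
#' Pairwise comparison of predicted and census values (typically county SU
#' totals). R2 is the one-minus-error-ratio form
#' `1 - sum((c - p)^2) / sum((c - mean(c))^2)` against the census variance —
#' not a squared correlation — so a biased predictor can score negative.
#' With a constant census vector R2 is undefined and returned as `NA` (RMSE
#' and MAE are still meaningful).
#'
#' @param predicted,census numeric vectors of equal length >= 2.
#' @return list with `r2`, `rmse`, `mae`, `n`.
#' @examples
#' spatial_metrics(c(12, 18, 33), c(10, 20, 30))
#' @export
spatial_metrics <- function(predicted, census) {
  if (length(predicted) != length(census)) stop("length mismatch")
  n <- length(census)
  if (n < 2L) stop("need at least 2 paired values")
  err <- census - predicted
  ss_res <- sum(err^2)
  ss_tot <- sum((census - mean(census))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(r2 = r2, rmse = sqrt(ss_res / n), mae = mean(abs(err)), n = n)
}

#' Nash-Sutcliffe efficiency of a predicted time series
#'
#' `NSE = 1 - sum_t (p_t - c_t)^2 / sum_t (c_t - mean(c))^2`; 1 means the
#' predicted series reproduces the census temporal trend exactly, 0 means it
#' is no better than the census mean. Same functional form as the spatial
#' R2, applied along the time axis. Constant census series -> `NA`
#' (undefined).
#'
#' @param predicted,census numeric yearly series of equal length >= 2.
#' @return the NSE (scalar, <= 1, possibly negative, `NA` if undefined).
#' @export
nse <- function(predicted, census) {
  if (length(predicted) != length(census)) stop("length mismatch")
  if (length(census) < 2L) stop("need at least 2 time steps")
  ss_tot <- sum((census - mean(census))^2)
  if (ss_tot <= 0) return(NA_real_)
  1 - sum((predicted - census)^2) / ss_tot
}

#' Mean relative error in percent
#'
#' `MRE = mean_j |c_j - p_j| / c_j * 100` over counties with census > 0;
#' zero-census counties cannot contribute a relative error and are excluded,
#' their count reported in the `n_excluded` attribute.
#'
#' @param predicted,census numeric vectors of equal length.
#' @return MRE in percent, with attributes `n_used` and `n_excluded`.
#' @examples
#' mre(c(90, 220), c(100, 200))  # 10
#' @export
mre <- function(predicted, census) {
  if (length(predicted) != length(census)) stop("length mismatch")
  keep <- census > 0
  if (!any(keep)) stop("all census values are zero; MRE undefined")
  value <- mean(abs((census[keep] - predicted[keep]) / census[keep])) * 100
  structure(value, n_used = sum(keep), n_excluded = sum(!keep))
}

#' Bundle the validation metrics into one report
#'
#' @param predicted,census paired vectors at the chosen level.
#' @param level one of "county", "pixel", "regional-year".
#' @return list of class `validation_report`: `r2`, `rmse`, `mae`,
#'   `mre_percent` (spatial levels) or `nse` (regional-year), `n`, `level`.
#' @export
validation_report <- function(predicted, census,
                              level = c("county", "pixel", "regional-year")) {
  level <- match.arg(level)
  if (level == "regional-year") {
    rep <- list(nse = nse(predicted, census), n = length(census),
                level = level)
  } else {
    sm <- spatial_metrics(predicted, census)
    rep <- c(sm[c("r2", "rmse", "mae")],
             list(mre_percent = as.numeric(mre(predicted, census)),
                  n = sm$n, level = level))
  }
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation (", x$level, ", n = ", x$n, "):\n", sep = "")
  if (!is.null(x$nse)) {
    cat(sprintf("  NSE = %.4f\n", x$nse))
  } else {
    cat(sprintf("  R2 = %.4f  RMSE = %.4g  MAE = %.4g  MRE = %.2f%%\n",
                x$r2, x$rmse, x$mae, x$mre_percent))
  }
  invisible(x)
}
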