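#' Theoretical livestock carrying-capacity threshold
#'
#' Standard forage-balance form: the stocking density a pasture sustains is
#' the usable forage divided by one sheep unit's annual intake,
#' `threshold = forage_yield * utilization / (intake * grazing_days)` in
#' SU/hm2. Used to derive partition thresholds when the published per-type
#' values are not applicable; [default_partition_spec()] carries the
#' published ones (0.43 / 0.35 / 0.21 SU/hm2).
#'
#' @param forage_yield annual forage yield, kg/hm2.
#' @param utilization usable fraction of the yield, in (0, 1].
#' @param intake daily dry-matter intake per sheep unit, kg/SU/day.
#' @param grazing_days grazing days per year.
#' @return carrying capacity in SU/hm2.
#' @examples
#' capacity_threshold(1000, 0.5, 1.8, 365)  # ~0.761
#' @export
capacity_threshold <- function(forage_yield, utilization, intake,
                               grazing_days) {
  if (any(c(forage_yield, utilization, intake, grazing_days) <= 0))
    stop("all carrying-capacity parameters must be > 0")
  if (utilization > 1) stop("utilization must be in (0, 1]")
  forage_yield * utilization / (intake * grazing_days)
}

#' Partition specification: per-type density thresholds
#'
#' Carrying-capacity thresholds (SU/hm2) separating low- from high-density
#' training samples per grassland type, plus the pixel area used to convert
#' the SU/pixel response to SU/hm2. Defaults are the published values for
#' alpine meadow (0.43), alpine steppe (0.35) and alpine desert steppe
#' (0.21).
#'
#' @param thresholds named numeric, SU/hm2, one entry per grassland type
#'   code in [grassland_levels()] order.
#' @param pixel_area_hm2 pixel area, hm2.
#' @return list of class `partition_spec`.
#' @export
default_partition_spec <- function(thresholds = c(alpine_meadow = 0.43,
                                                  alpine_steppe = 0.35,
                                                  alpine_desert_steppe = 0.21),
                                   pixel_area_hm2 = 100) {
  if (any(thresholds <= 0)) stop("thresholds must be > 0")
  structure(list(thresholds = thresholds, pixel_area_hm2 = pixel_area_hm2),
            class = "partition_spec")
}

# threshold (SU/hm2) for each integer-coded grassland type
threshold_for_type <- function(type_code, spec) {
  lev <- grassland_levels()
  if (any(type_code < 1L | type_code > length(lev), na.rm = TRUE) ||
      anyNA(type_code))
    stop("unknown grassland type code(s): ",
         paste(unique(type_code[is.na(type_code) | type_code < 1L |
                                  type_code > length(lev)]), collapse = ", "))
  missing_thr <- setdiff(lev[sort(unique(type_code))], names(spec$thresholds))
  if (length(missing_thr))
    stop("no threshold for grassland type(s): ",
         paste(missing_thr, collapse = ", "))
  unname(spec$thresholds[lev[type_code]])
}

#' Split training samples at the carrying-capacity threshold
#'
#' A row goes to the `high` subset iff its response density (SU/pixel
#' converted to SU/hm2 via `spec$pixel_area_hm2`) strictly exceeds the
#' threshold of its grassland type; boundary rows go `low` (documented
#' tie-break). Both subsets keep all columns.
#'
#' @param table a `group_feature_table` (needs `response` and
#'   `grassland_type`).
#' @param spec a [default_partition_spec()].
#' @return list with `low` and `high` data.frames.
#' @export
partition_samples <- function(table, spec = default_partition_spec()) {
  stopifnot(is.data.frame(table),
            all(c("response", "grassland_type") %in% names(table)))
  thr <- threshold_for_type(table$grassland_type, spec)
  density_hm2 <- table$response / spec$pixel_area_hm2
  high <- density_hm2 > thr
  list(low = table[!high, , drop = FALSE], high = table[high, , drop = FALSE])
}

feature_columns <- function(table) {
  setdiff(names(table),
          c("county_id", "group_id", "n_pixels", "response", "grassland_type"))
}

# fit one random forest on log1p(response) ~ features, with held-out metrics
fit_submodel <- function(table, feature_names, split_seed, model_seed,
                         num_trees) {
  n <- nrow(table)
  df <- table[, feature_names, drop = FALSE]
  df$.y <- log1p(table$response)
  set.seed(split_seed)
  test_idx <- sample.int(n, max(1L, floor(n / 4)))
  train <- df[-test_idx, , drop = FALSE]
  test <- df[test_idx, , drop = FALSE]
  rf <- ranger::ranger(
    dependent.variable.name = ".y", data = train,
    num.trees = num_trees, importance = "impurity",
    seed = model_seed, num.threads = 1L
  )
  pred <- expm1(stats::predict(rf, data = test,
                               num.threads = 1L)$predictions)
  obs <- expm1(test$.y)
  holdout <- if (length(obs) >= 2L) spatial_metrics(pred, obs)
             else list(r2 = NA_real_, rmse = abs(pred - obs),
                       mae = abs(pred - obs), n = 1L)
  list(rf = rf, holdout = holdout, n_train = nrow(train), n_test = nrow(test))
}

#' Fit a grazing spatialization model (variants M1-M4)
#'
#' Trains the random-forest spatializer on a feature table. The four
#' variants of the method ladder are:
#' \describe{
#'   \item{M1}{single RF on county-level (traditional) features;}
#'   \item{M2}{two RFs partitioned at the carrying-capacity threshold,
#'     county-level features;}
#'   \item{M3}{single RF on group-level cross-scale features;}
#'   \item{M4}{partitioned RFs on cross-scale features (the full method).}
#' }
#' The caller supplies the matching table ([county_feature_table()] for
#' M1/M2, [extract_csf()] for M3/M4). The response is modelled as
#' `log1p(SU/pixel)`; samples are split 3:1 into training and testing at
#' `split_seed` and held-out R2/RMSE/MAE are recorded per submodel. A
#' partition left with fewer than `min_rows` samples triggers a single-model
#' fallback (warning).
#'
#' @param table training `group_feature_table`.
#' @param variant one of "M1", "M2", "M3", "M4".
#' @param spec [default_partition_spec()]; needed for partitioned variants
#'   and for prediction-time routing.
#' @param split_seed,model_seed integer seeds for the 3:1 split and the
#'   forests; fixed seeds make refits bit-identical.
#' @param num_trees trees per forest (default 500).
#' @param min_rows minimum samples per fitted submodel (default 8).
#' @return object of class `spatializer`: submodels (`pooled` or
#'   `low`/`high` + `router`), feature names, transform metadata, seeds,
#'   importances, held-out metrics.
#' @export
fit_spatializer <- function(table, variant = c("M4", "M1", "M2", "M3"),
                            spec = default_partition_spec(),
                            split_seed = 1L, model_seed = 1L,
                            num_trees = 500L, min_rows = 8L) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(table), "response" %in% names(table))
  feats <- feature_columns(table)
  if (length(feats) == 0L) stop("table has no feature columns")
  partitioned <- variant %in% c("M2", "M4")
  fallback <- FALSE
  if (partitioned) {
    parts <- partition_samples(table, spec)
    if (nrow(parts$low) < min_rows || nrow(parts$high) < min_rows) {
      warning("partition '",
              if (nrow(parts$low) < nrow(parts$high)) "low" else "high",
              "' has fewer than ", min_rows,
              " samples; falling back to a single model")
      fallback <- TRUE
    }
  }
  if (nrow(table) < min_rows)
    stop("fewer than ", min_rows, " training samples")

  submodels <- list()
  if (partitioned && !fallback) {
    submodels$low <- fit_submodel(parts$low, feats, split_seed, model_seed,
                                  num_trees)
    submodels$high <- fit_submodel(parts$high, feats, split_seed,
                                   model_seed + 1L, num_trees)
    submodels$router <- fit_submodel(table, feats, split_seed, model_seed + 2L,
                                     num_trees)
  } else {
    submodels$pooled <- fit_submodel(table, feats, split_seed, model_seed,
                                     num_trees)
  }
  importances <- lapply(submodels, function(s) s$rf$variable.importance)
  holdout <- lapply(submodels, `[[`, "holdout")
  structure(
    list(variant = variant, submodels = submodels, spec = spec,
         feature_names = feats,
         response_transform = list(family = "natural-log", offset = 1),
         split_seed = split_seed, model_seed = model_seed,
         num_trees = num_trees, partition_fallback = fallback,
         importances = importances, holdout = holdout,
         n_samples = nrow(table)),
    class = "spatializer"
  )
}

#' @export
print.spatializer <- function(x, ...) {
  cat(sprintf("Grazing spatializer %s: %d training samples, %d trees\n",
              x$variant, x$n_samples, x$num_trees))
  cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  for (nm in setdiff(names(x$holdout), "router")) {
    h <- x$holdout[[nm]]
    if (!is.null(h$r2) && length(h$r2) == 1L && is.finite(h$r2))
      cat(sprintf("  held-out (%s): R2 = %.3f, RMSE = %.3g, n = %d\n",
                  nm, h$r2, h$rmse, h$n))
  }
  if (isTRUE(x$partition_fallback))
    cat("  note: partition fallback to a single model\n")
  invisible(x)
}

#' Predict pixel-level grazing density from a fitted spatializer
#'
#' Builds the per-pixel feature vectors from the covariate stack, routes
#' each suitable pixel to a submodel, inverts the log transform and clips at
#' zero. Partitioned variants route by a provisional density from the pooled
#' router forest: a pixel goes to the `high` forest iff the provisional
#' density (SU/hm2) exceeds its grassland type's threshold.
#'
#' @param object a `spatializer`.
#' @param covariates named list of raster fields covering every feature.
#' @param grassland_type integer-coded type raster field.
#' @param mask logical matrix or `suitability_mask`; `NULL` means all
#'   non-`NA` covariate pixels.
#' @param ... unused.
#' @return numeric matrix of predicted SU/pixel (`NA` off-mask).
#' @export
predict.spatializer <- function(object, covariates, grassland_type,
                                mask = NULL, ...) {
  absent <- setdiff(object$feature_names, names(covariates))
  if (length(absent))
    stop("covariate stack is missing feature(s): ",
         paste(absent, collapse = ", "))
  do.call(check_same_lattice, c(list(grassland_type),
                                covariates[object$feature_names]))
  dims <- dim(grassland_type)
  if (inherits(mask, "suitability_mask")) mask <- mask$mask
  if (is.null(mask)) mask <- matrix(TRUE, dims[1L], dims[2L])
  check_same_lattice(grassland_type, mask)

  X <- as.data.frame(lapply(covariates[object$feature_names], as.vector))
  ok <- as.vector(mask) %in% TRUE & stats::complete.cases(X)
  out <- matrix(NA_real_, dims[1L], dims[2L])
  if (!any(ok)) return(out)
  Xok <- X[ok, , drop = FALSE]

  predict_one <- function(sub)
    pmax(expm1(stats::predict(sub$rf, data = Xok,
                              num.threads = 1L)$predictions), 0)

  if (!is.null(object$submodels$pooled)) {
    out[ok] <- predict_one(object$submodels$pooled)
    return(out)
  }
  provisional <- predict_one(object$submodels$router)
  thr <- threshold_for_type(as.vector(grassland_type)[ok], object$spec)
  high <- provisional / object$spec$pixel_area_hm2 > thr
  pred <- numeric(sum(ok))
  if (any(!high)) {
    low_pred <- pmax(expm1(stats::predict(
      object$submodels$low$rf, data = Xok[!high, , drop = FALSE],
      num.threads = 1L)$predictions), 0)
    pred[!high] <- low_pred
  }
  if (any(high)) {
    high_pred <- pmax(expm1(stats::predict(
      object$submodels$high$rf, data = Xok[high, , drop = FALSE],
      num.threads = 1L)$predictions), 0)
    pred[high] <- high_pred
  }
  out[ok] <- pred
  out
}

#' County residual correction with mass conservation
#'
#' Adds each county's residual `R_j = census_j / n_j - mean(su_raw)` to all
#' of the county's pixels, so corrected county means equal census means
#' exactly. Where the additive shift would drive pixels negative, values are
#' clipped at zero and the clipped mass is re-spread proportionally over the
#' remaining pixels (iterated to `tol`), preserving both nonnegativity and
#' the county total. Counties absent from the census are left uncorrected
#' and reported.
#'
#' @param su_raw predicted SU/pixel matrix (`NA` off-mask).
#' @param census a [census_table()].
#' @param zones integer county-label raster field.
#' @param year census year to correct against (default: single year
#'   present).
#' @param tol relative tolerance on each county total (default 1e-9).
#' @param max_iter safety cap on the clip/re-spread loop.
#' @return object of class `gridded_grazing`: list with `su_raw`,
#'   `su_corrected`, `year`, `uncorrected_counties`.
#' @export
residual_correct <- function(su_raw, census, zones, year = NULL,
                             tol = 1e-9, max_iter = 100L) {
  stopifnot(inherits(census, "census_table"))
  check_same_lattice(su_raw, zones)
  if (is.null(year)) {
    yrs <- unique(census$year)
    if (length(yrs) != 1L) stop("census covers several years; pass `year`")
    year <- yrs
  }
  rows <- census[census$year == year, , drop = FALSE]
  totals <- stats::setNames(rows$su_total, rows$county_id)
  corrected <- su_raw
  uncorrected <- integer(0)
  for (cid in sort(unique(zones[!is.na(zones)]))) {
    idx <- which(zones == cid & !is.na(su_raw))
    if (length(idx) == 0L) next
    key <- as.character(cid)
    if (!key %in% names(totals)) {
      uncorrected <- c(uncorrected, cid)
      next
    }
    target <- totals[[key]]
    x <- su_raw[idx] + (target / length(idx) - mean(su_raw[idx]))
    iter <- 0L
    while (any(x < 0) && iter < max_iter) {
      x <- pmax(x, 0)
      s <- sum(x)
      if (s <= 0) {
        x <- rep(target / length(x), length(x))
      } else {
        x <- x * target / s
      }
      iter <- iter + 1L
      if (abs(sum(x) - target) <= tol * max(1, abs(target))) break
    }
    corrected[idx] <- x
  }
  structure(list(su_raw = su_raw, su_corrected = corrected, year = year,
                 uncorrected_counties = uncorrected),
            class = "gridded_grazing")
}

#' @export
print.gridded_grazing <- function(x, ...) {
  cat(sprintf("Gridded grazing, year %s: %d pixels, %.1f SU corrected total\n",
              format(x$year), sum(!is.na(x$su_corrected)),
              sum(x$su_corrected, na.rm = TRUE)))
  if (length(x$uncorrected_counties))
    cat("  uncorrected counties:",
        paste(x$uncorrected_counties, collapse = ", "), "\n")
  invisible(x)
}
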