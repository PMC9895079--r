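#' Davies-Bouldin index of a 1-D grouping
#'
#' `DBI_k = (1/k) * sum_x max_{y != x} (a_x + a_y) / |d_x - d_y|`, where
#' `a_x` is the mean absolute distance of group x's members to the group
#' centroid and `d_x` the centroid itself. Lower is better: tight,
#' well-separated groups. Two coincident centroids make the score infinite
#' (degenerate grouping).
#'
#' @param values numeric vector.
#' @param labels group assignment, same length; every group nonempty.
#' @return the DBI (may be `Inf` when centroids coincide).
#' @examples
#' davies_bouldin(c(0, 0, 10, 10), c(1, 1, 2, 2))  # 0
#' @export
davies_bouldin <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop("Davies-Bouldin index needs at least 2 groups")
  centroid <- tapply(values, labels, mean)
  within <- tapply(abs(values - centroid[labels]), labels, mean)
  terms <- vapply(seq_len(k), function(x) {
    others <- setdiff(seq_len(k), x)
    sep <- abs(centroid[x] - centroid[others])
    ratio <- (within[x] + within[others]) / sep   # sep 0 -> Inf (or NaN if 0/0)
    ratio[is.nan(ratio)] <- Inf
    max(ratio)
  }, numeric(1L))
  mean(terms)
}

#' Select the number of within-county groups by Davies-Bouldin minimization
#'
#' Agglomerative (Ward) hierarchical clustering of 1-D values, cut at each
#' candidate k; the selected k minimizes the Davies-Bouldin index, ties
#' resolved to the smaller k for parsimony. Hierarchical clustering is
#' deterministic, so repeated calls agree. Degenerate inputs (fewer than two
#' points, or all values identical) collapse to a single group.
#'
#' @param values numeric vector.
#' @param k_range candidate group counts (default 2:6), capped at
#'   `length(values)`; `k_range = 1` forces the single-group (county-mean)
#'   path.
#' @return object of class `cluster_selection`: list with `k_selected`,
#'   `k_candidates`, `dbi_values`, `labels` (assignment for the selected k).
#' @examples
#' v <- c(rnorm(10), rnorm(10, 50), rnorm(10, 100))
#' select_group_count(v)$k_selected  # 3
#' @export
select_group_count <- function(values, k_range = 2:6) {
  n <- length(values)
  degenerate <- function() {
    structure(list(k_selected = 1L, k_candidates = integer(0),
                   dbi_values = numeric(0), labels = rep(1L, n)),
              class = "cluster_selection")
  }
  if (n < 2L || max(values) - min(values) < 1e-12) return(degenerate())
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 1L & k_range <= n]
  if (length(k_range) == 0L || all(k_range == 1L)) return(degenerate())
  k_range <- k_range[k_range >= 2L]
  hc <- stats::hclust(stats::dist(values), method = "ward.D2")
  cuts <- stats::cutree(hc, k = k_range)
  if (length(k_range) == 1L) cuts <- matrix(cuts, ncol = 1L)
  dbi <- vapply(seq_along(k_range),
                function(i) davies_bouldin(values, cuts[, i]),
                numeric(1L))
  if (all(!is.finite(dbi))) return(degenerate())
  best <- which.min(dbi)   # first minimum = smallest k on ties
  structure(list(k_selected = k_range[best], k_candidates = k_range,
                 dbi_values = dbi, labels = as.integer(cuts[, best])),
            class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat("Group count selected:", x$k_selected, "\n")
  if (length(x$k_candidates))
    cat("  DBI:", paste(sprintf("k=%d: %.3g", x$k_candidates, x$dbi_values),
                        collapse = ", "), "\n")
  invisible(x)
}

# modal value of an integer/character vector (ties -> first-sorted level)
modal_value <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1L]
}

#' Extract cross-scale features (group-level training samples)
#'
#' Decomposes each county's mean into group-level means: the pre-distributed
#' pixel SU values are clustered within the county ([select_group_count()]),
#' and one training row per group records the group mean response
#' (SU/pixel), the group means of every covariate, the modal grassland type
#' and the pixel count. Counties with fewer pixels than the smallest
#' candidate k (or `k_range = 1`) contribute a single county-mean row — the
#' traditional (county-level) feature table, so the same routine builds the
#' training data for all model variants.
#'
#' @param dist a [dasymetric_distribute()] result (or bare SU matrix).
#' @param covariates named list of covariate raster fields.
#' @param zones integer county-label raster field.
#' @param grassland_type integer raster field coded by [grassland_levels()].
#' @param k_range candidate group counts per county; `1` collapses every
#'   county to its mean (traditional features).
#' @return data.frame of class `group_feature_table` with columns
#'   `county_id`, `group_id`, `n_pixels`, `response`, `grassland_type`, and
#'   one column per covariate; attribute `diagnostics` holds each county's
#'   selected k and DBI curve.
#' @examples
#' zones <- matrix(1L, 2, 2)
#' su <- matrix(c(1, 1, 9, 9), 2, 2)
#' cov1 <- matrix(c(2, 2, 4, 4), 2, 2)
#' gt <- matrix(1L, 2, 2)
#' extract_csf(su, list(cov1 = cov1), zones, gt)
#' @export
extract_csf <- function(dist, covariates, zones, grassland_type,
                        k_range = 2:6) {
  su <- if (inherits(dist, "distributed_density")) dist$su else dist
  do.call(check_same_lattice, c(list(su, zones, grassland_type), covariates))
  if (is.null(names(covariates)) || any(names(covariates) == ""))
    stop("covariates must be a named list")
  rows <- list()
  diagnostics <- list()
  skipped <- integer(0)
  for (cid in sort(unique(zones[!is.na(zones)]))) {
    idx <- which(zones == cid & !is.na(su))
    if (length(idx) == 0L) {
      skipped <- c(skipped, cid)
      next
    }
    sel <- select_group_count(su[idx], k_range = k_range)
    diagnostics[[as.character(cid)]] <- list(
      k_selected = sel$k_selected, k_candidates = sel$k_candidates,
      dbi_values = sel$dbi_values, n_pixels = length(idx))
    for (g in sort(unique(sel$labels))) {
      gidx <- idx[sel$labels == g]
      row <- data.frame(county_id = cid, group_id = g,
                        n_pixels = length(gidx),
                        response = mean(su[gidx]),
                        grassland_type = modal_value(grassland_type[gidx]),
                        stringsAsFactors = FALSE)
      for (nm in names(covariates)) row[[nm]] <- mean(covariates[[nm]][gidx])
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) stop("no county contributed any masked pixel")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$grassland_type <- as.integer(out$grassland_type)
  attr(out, "diagnostics") <- diagnostics
  attr(out, "skipped_counties") <- skipped
  class(out) <- c("group_feature_table", "data.frame")
  out
}

#' Traditional county-level feature table
#'
#' The county-mean counterpart of [extract_csf()]: exactly one row per
#' county (its mean response and mean covariates) — the training table of
#' the traditional spatialization models.
#'
#' @inheritParams extract_csf
#' @return `group_feature_table` with one row per county.
#' @export
county_feature_table <- function(dist, covariates, zones, grassland_type) {
  extract_csf(dist, covariates, zones, grassland_type, k_range = 1L)
}

#' Write cluster diagnostics (selected k, DBI curves) as JSON
#'
#' @param table a `group_feature_table`.
#' @param path output JSON file.
#' @export
write_cluster_diagnostics <- function(table, path) {
  jsonlite::write_json(attr(table, "diagnostics"), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
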