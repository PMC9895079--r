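#' Extract theoretically suitable grazing areas
#'
#' Decision-tree masking: start from the grassland extent and remove, in
#' order, extremely-high-altitude pixels, pixels adjacent to towns, and the
#' core areas of national nature reserves. The final mask is where grazing
#' can occur; every removal step is logged with its pixel count.
#'
#' Altitude and town-proximity cutoffs are deliberately explicit parameters
#' (defaults 5500 m and 2 km): they are management choices, and every run
#' records the values used in the criteria log attributes.
#'
#' @param grassland logical raster field: the grassland extent.
#' @param elevation numeric raster field, metres; `NULL` skips the rule
#'   (with a warning).
#' @param town_distance numeric raster field, metres to the nearest town;
#'   `NULL` skips the rule.
#' @param reserve_core logical raster field: national nature-reserve core
#'   areas; `NULL` skips the rule.
#' @param thresholds list with `max_elevation` (m) and `min_town_distance`
#'   (m).
#' @return object of class `suitability_mask`: list with `mask` (logical
#'   matrix) and `criteria_log` (data.frame: rule, pixels_removed, applied),
#'   plus the thresholds as an attribute. The mask itself is independent of
#'   rule order; only the per-rule removal counts depend on it.
#' @examples
#' g <- matrix(TRUE, 4, 4)
#' elev <- matrix(5000, 4, 4); elev[1, 1] <- 6000
#' build_suitability_mask(g, elevation = elev)$criteria_log
#' @export
build_suitability_mask <- function(grassland, elevation = NULL,
                                   town_distance = NULL, reserve_core = NULL,
                                   thresholds = list(max_elevation = 5500,
                                                     min_town_distance = 2000)) {
  stopifnot(is.matrix(grassland))
  check_same_lattice(grassland, elevation, town_distance, reserve_core)
  mask <- !is.na(grassland) & grassland
  log_rows <- list()
  apply_rule <- function(rule, layer, exclude) {
    if (is.null(layer)) {
      warning("layer for rule '", rule, "' missing; rule skipped")
      log_rows[[length(log_rows) + 1L]] <<- data.frame(
        rule = rule, pixels_removed = 0L, applied = FALSE)
      return(invisible(NULL))
    }
    drop <- mask & !is.na(exclude) & exclude
    mask[drop] <<- FALSE
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      rule = rule, pixels_removed = sum(drop), applied = TRUE)
    invisible(NULL)
  }
  apply_rule("extreme_altitude", elevation,
             elevation > thresholds$max_elevation)
  apply_rule("town_proximity", town_distance,
             town_distance < thresholds$min_town_distance)
  apply_rule("reserve_core", reserve_core,
             !is.na(reserve_core) & reserve_core)
  structure(
    list(mask = mask, criteria_log = do.call(rbind, log_rows)),
    thresholds = thresholds,
    class = "suitability_mask"
  )
}

#' @export
print.suitability_mask <- function(x, ...) {
  cat("Suitable grazing area:", sum(x$mask), "pixels\n")
  print(x$criteria_log)
  invisible(x)
}

#' Write the suitability criteria log as JSON
#'
#' @param mask a `suitability_mask`.
#' @param path output JSON file.
#' @export
write_criteria_log <- function(mask, path) {
  stopifnot(inherits(mask, "suitability_mask"))
  jsonlite::write_json(
    list(thresholds = attr(mask, "thresholds"),
         criteria = mask$criteria_log,
         suitable_pixels = sum(mask$mask)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
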