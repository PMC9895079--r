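#' Standard sheep-unit conversion coefficients
#'
#' Species-to-sheep-equivalent factors following the Chinese rangeland
#' carrying-capacity standard (NY/T 635-2015): one sheep counts 1, a goat
#' 0.8, cattle and yaks 5, horses and mules 6, donkeys 3, camels 7.
#' Overridable because national standards get revised.
#'
#' @return named numeric vector of coefficients.
#' @export
sheep_unit_coefficients <- function() {
  c(sheep = 1, goats = 0.8, cattle = 5, yaks = 5,
    horses = 6, donkeys = 3, mules = 6, camels = 7)
}

#' Convert livestock head counts to standard sheep units (SU)
#'
#' `SU = N_sheep + 0.8 N_goats + 5 N_cattle + 5 N_yaks + 6 N_horses +
#' 3 N_donkeys + 6 N_mules + 7 N_camels`. The conversion is linear in the
#' counts, so it can be applied per herd, per county or per province
#' interchangeably.
#'
#' @param counts named numeric vector, list or data.frame with (a subset of)
#'   the species in [sheep_unit_coefficients()]; a data.frame is converted
#'   row-wise. Absent species count as zero; unknown names are an error.
#' @param coefficients override for the conversion factors.
#' @return numeric SU total (vector of length `nrow(counts)` for a
#'   data.frame).
#' @examples
#' to_sheep_units(c(goats = 10))            # 8
#' to_sheep_units(c(sheep = 100, yaks = 10)) # 150
#' @export
to_sheep_units <- function(counts, coefficients = sheep_unit_coefficients()) {
  if (is.data.frame(counts)) {
    species <- intersect(names(counts), names(coefficients))
    extra <- setdiff(names(counts), names(coefficients))
    if (length(extra))
      stop("unknown species column(s): ", paste(extra, collapse = ", "))
    m <- as.matrix(counts[species])
    if (any(m < 0, na.rm = TRUE)) stop("livestock counts must be nonnegative")
    return(as.numeric(m %*% coefficients[species]))
  }
  counts <- unlist(counts)
  extra <- setdiff(names(counts), names(coefficients))
  if (length(extra))
    stop("unknown species: ", paste(extra, collapse = ", "))
  if (any(counts < 0)) stop("livestock counts must be nonnegative")
  sum(counts * coefficients[names(counts)])
}

#' County-by-year census tables
#'
#' A census table holds one row per (county, year): the county's standard
#' sheep-unit total (`su_total`, SU per county per year) and a `provenance`
#' flag distinguishing recorded yearbook values from interpolated ones.
#'
#' @param x data.frame with columns `county_id`, `year`, `su_total` and
#'   optionally `provenance` (defaults to "recorded").
#' @return validated data.frame of class `census_table`.
#' @export
census_table <- function(x) {
  stopifnot(is.data.frame(x))
  needed <- c("county_id", "year", "su_total")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols))
    stop("census table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!"provenance" %in% names(x)) x$provenance <- "recorded"
  if (any(x$su_total < 0, na.rm = TRUE)) stop("su_total must be >= 0")
  if (anyDuplicated(x[c("county_id", "year")]))
    stop("(county_id, year) pairs must be unique")
  if (!all(x$provenance %in% c("recorded", "interpolated")))
    stop("provenance must be 'recorded' or 'interpolated'")
  x <- x[order(x$county_id, x$year), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("census_table", "data.frame")
  x
}

#' @rdname census_table
#' @param path CSV file with the census-table columns.
#' @export
read_census_csv <- function(path) {
  census_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname census_table
#' @param table a `census_table`.
#' @export
write_census_csv <- function(table, path) {
  stopifnot(inherits(table, "census_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Fill missing census years from a parent-level series
#'
#' County-years absent from the table over `years` are approximated from the
#' temporal trend of a parent (city/province) SU series: the gap year gets
#' the county's nearest recorded value scaled by the parent series' ratio
#' between the two years. Without a parent series the fallback is linear
#' interpolation between the county's recorded years (constant extension
#' beyond them). Recorded rows are never altered; filled rows are flagged
#' `provenance = "interpolated"`.
#'
#' @param table a [census_table()].
#' @param years integer vector of years the output must cover (default: the
#'   full range present in `table`).
#' @param parent_series optional data.frame with columns `year`, `su_total`
#'   (or a year-named numeric vector) at the parent administrative level; it
#'   must cover every gap year and its anchor years.
#' @return gap-free `census_table` over `years` for every county in `table`.
#' @examples
#' tab <- census_table(data.frame(county_id = 1, year = c(1, 3),
#'                                su_total = c(100, 200)))
#' fill_missing_years(tab)  # year 2 -> 150 by linear interpolation
#' @export
fill_missing_years <- function(table, years = NULL, parent_series = NULL) {
  stopifnot(inherits(table, "census_table"))
  if (is.null(years)) years <- seq(min(table$year), max(table$year))
  if (!is.null(parent_series)) {
    if (is.data.frame(parent_series)) {
      parent <- stats::setNames(parent_series$su_total, parent_series$year)
    } else {
      parent <- parent_series
    }
    if (is.null(names(parent))) stop("parent_series must be year-named")
  }
  out <- list()
  for (cid in unique(table$county_id)) {
    rows <- table[table$county_id == cid, , drop = FALSE]
    recorded <- rows[rows$provenance == "recorded", , drop = FALSE]
    if (nrow(recorded) == 0L)
      stop("county ", cid, " has no recorded year to anchor interpolation")
    gaps <- setdiff(years, rows$year)
    filled <- rows[rows$year %in% years, , drop = FALSE]
    for (t in gaps) {
      if (!is.null(parent_series)) {
        anchor <- recorded$year[which.min(abs(recorded$year - t))]
        pt <- parent[as.character(t)]
        pa <- parent[as.character(anchor)]
        if (is.na(pt) || is.na(pa))
          stop("parent series does not cover years ", t, " and ", anchor)
        value <- recorded$su_total[recorded$year == anchor] * pt / pa
      } else {
        value <- stats::approx(recorded$year, recorded$su_total,
                               xout = t, rule = 2)$y
      }
      filled <- rbind(filled, data.frame(
        county_id = cid, year = t, su_total = as.numeric(value),
        provenance = "interpolated", stringsAsFactors = FALSE
      ))
    }
    out[[length(out) + 1L]] <- filled
  }
  census_table(do.call(rbind, out))
}
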