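#' Raster fields
#'
#' A raster field in this package is a plain numeric (or logical/integer)
#' matrix on a shared lattice; `NA` is the nodata value. All pipeline stages
#' require their inputs to share one lattice, checked with
#' [check_same_lattice()]. Multi-temporal stacks (NDVI series, per-year truth)
#' are lists of such matrices, one per time step.
#'
#' @name raster-fields
NULL

#' Check that raster fields share one lattice
#'
#' @param ... matrices (raster fields); `NULL` entries are skipped.
#' @return invisibly, the common `dim()`.
#' @export
check_same_lattice <- function(...) {
  fields <- Filter(Negate(is.null), list(...))
  if (length(fields) == 0L) stop("no raster fields supplied")
  dims <- lapply(fields, dim)
  if (any(vapply(dims, is.null, logical(1L))))
    stop("raster fields must be matrices")
  ref <- dims[[1L]]
  ok <- vapply(dims, function(d) identical(d, ref), logical(1L))
  if (!all(ok)) stop("raster fields are not on a shared lattice: dims differ")
  invisible(ref)
}

#' Zonal sum / mean of a raster field over labelled zones
#'
#' Sums (or averages) `x` over each zone label, ignoring pixels where either
#' `x` or `zones` is nodata.
#'
#' @param x numeric raster field.
#' @param zones integer raster field of zone labels (e.g. county ids).
#' @return named numeric vector, one entry per zone label present.
#' @export
zonal_sum <- function(x, zones) {
  check_same_lattice(x, zones)
  keep <- !is.na(x) & !is.na(zones)
  tapply(x[keep], zones[keep], sum)
}

#' @rdname zonal_sum
#' @export
zonal_mean <- function(x, zones) {
  check_same_lattice(x, zones)
  keep <- !is.na(x) & !is.na(zones)
  tapply(x[keep], zones[keep], mean)
}

#' Read / write ESRI ASCII grid rasters
#'
#' Plain-text raster interchange: a 6-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values, top row first. Any GIS reads this format.
#'
#' @param x numeric matrix (raster field); `NA` written as the nodata value.
#' @param path file path.
#' @param xllcorner,yllcorner,cellsize grid georeference (defaults suit
#'   synthetic landscapes indexed in pixel units).
#' @param nodata value standing in for `NA` on disk.
#' @return `read_ascii_grid()` returns the matrix with `NA` nodata;
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
write_ascii_grid <- function(x, path, xllcorner = 0, yllcorner = 0,
                             cellsize = 1, nodata = -9999) {
  stopifnot(is.matrix(x))
  hdr <- c(
    paste("ncols", ncol(x)),
    paste("nrows", nrow(x)),
    paste("xllcorner", xllcorner),
    paste("yllcorner", yllcorner),
    paste("cellsize", cellsize),
    paste("NODATA_value", nodata)
  )
  body <- apply(x, 1L, function(row) {
    row[is.na(row)] <- nodata
    paste(format(row, trim = TRUE, scientific = FALSE, digits = 12),
          collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, character(1L), 1L))
  vals <- as.numeric(vapply(hdr, `[`, character(1L), 2L))
  names(vals) <- keys
  nr <- as.integer(vals[["nrows"]])
  nc <- as.integer(vals[["ncols"]])
  nodata <- vals[["nodata_value"]]
  body <- lines[-(1:6)]
  m <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    row <- as.numeric(strsplit(trimws(body[i]), "\\s+")[[1L]])
    m[i, ] <- row
  }
  m[m == nodata] <- NA_real_
  m
}
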