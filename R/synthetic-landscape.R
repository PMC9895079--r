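#' Configure a synthetic grazing landscape
#'
#' Builds the configuration object consumed by [generate_landscape()]. The
#' defaults define the package's reference test landscape: a 60x60 lattice
#' carved into 25 Voronoi counties, 8 spatially autocorrelated covariates,
#' and a pixel-level grazing density (standard sheep units, SU, per pixel)
#' driven by a sparse monotone combination of the first three covariates.
#'
#' `density_coef` publishes the generating coefficients so that variable
#' importance has a known ground truth: density is log-linear in a sparse
#' index of the first three covariates,
#' `exp(intercept + c1*x1 + c2*x2 + c3*x3 + c1c2*x1*x2) (+ noise)`, clipped
#' at 0 and scaled per year by `1 + year_trend*(year-1)`. The exponential
#' link gives the right-skewed density distribution grazing landscapes
#' actually show — most pixels lightly grazed, a heavy hotspot tail — which
#' is also the structure the spatializer's natural-log response transform
#' presumes; `intercept` is the log of the median density (SU/pixel).
#'
#' NDVI pairs are generated so that grazing depresses the observed series
#' below the potential one by a strictly increasing, saturating deficit
#' `ndvi_deficit_scale * d / (ndvi_deficit_halfsat + d)` of density `d`,
#' plus observation noise proportional to `noise_sd`.
#'
#' @param grid_rows,grid_cols lattice size in pixels.
#' @param n_counties number of Voronoi counties (>= 2, <= pixel count).
#' @param n_years number of census years (also the NDVI series length).
#' @param n_covariates number of covariate fields (>= 3; the first three
#'   carry the density signal).
#' @param noise_sd pixel density noise, SU/pixel; NDVI observation noise is
#'   `0.01 * noise_sd` so a noise-free run is noise-free throughout.
#' @param spatial_range Gaussian autocorrelation length, pixels.
#' @param seed integer RNG seed; the landscape is a pure function of the
#'   config.
#' @param pixel_area_hm2 declared pixel area in hectares (hm2), used for all
#'   SU/pixel to SU/hm2 conversions downstream.
#' @param density_coef named numeric: `intercept`, `c1`, `c2`, `c3`, `c1c2`.
#' @param ndvi_deficit_scale,ndvi_deficit_halfsat parameters of the monotone
#'   NDVI deficit function of density.
#' @param year_trend multiplicative density trend per year step.
#' @return object of class `landscape_config`.
#' @seealso [generate_landscape()]
#' @export
landscape_config <- function(grid_rows = 60, grid_cols = 60, n_counties = 25,
                             n_years = 3, n_covariates = 8, noise_sd = 2,
                             spatial_range = 6, seed = 42,
                             pixel_area_hm2 = 100,
                             density_coef = c(intercept = log(15), c1 = 0.8,
                                              c2 = 0.55, c3 = 0.35,
                                              c1c2 = 0.4),
                             ndvi_deficit_scale = 0.3,
                             ndvi_deficit_halfsat = 30,
                             year_trend = 0.05) {
  cfg <- list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    n_counties = as.integer(n_counties), n_years = as.integer(n_years),
    n_covariates = as.integer(n_covariates), noise_sd = noise_sd,
    spatial_range = spatial_range, seed = as.integer(seed),
    pixel_area_hm2 = pixel_area_hm2,
    density_coef = density_coef,
    ndvi_deficit_scale = ndvi_deficit_scale,
    ndvi_deficit_halfsat = ndvi_deficit_halfsat,
    year_trend = year_trend
  )
  n_pixels <- cfg$grid_rows * cfg$grid_cols
  if (cfg$n_counties < 2L) stop("n_counties must be >= 2")
  if (cfg$n_counties > n_pixels)
    stop("n_counties exceeds the pixel count of the lattice")
  if (cfg$n_years < 1L) stop("n_years must be >= 1")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$n_covariates < 3L) stop("n_covariates must be >= 3")
  required <- c("intercept", "c1", "c2", "c3", "c1c2")
  if (!all(required %in% names(cfg$density_coef)))
    stop("density_coef must name: ", paste(required, collapse = ", "))
  class(cfg) <- "landscape_config"
  cfg
}

#' Load a landscape configuration from a YAML file
#'
#' @param path YAML file whose keys are [landscape_config()] arguments.
#' @return `landscape_config` object.
#' @export
read_landscape_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  args <- yaml::yaml.load_file(path)
  if (!is.null(args$density_coef)) args$density_coef <- unlist(args$density_coef)
  do.call(landscape_config, args)
}

# Separable Gaussian smoothing with edge renormalization: convolve rows then
# columns with a truncated Gaussian kernel and divide by the smoothed
# all-ones field so edge pixels keep unit total weight.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(x) {
    n <- length(x)
    out <- stats::convolve(c(numeric(r), x, numeric(r)), rev(k), type = "open")
    out[(2 * r + 1):(2 * r + n)]
  }
  smooth_axis <- function(mm) {
    wts <- conv1(rep(1, ncol(mm)))
    t(apply(mm, 1L, function(x) conv1(x) / wts))
  }
  m <- smooth_axis(m)
  t(smooth_axis(t(m)))
}

# One standardized (mean 0, sd 1) spatially autocorrelated field.
autocorrelated_field <- function(nr, nc, sigma) {
  f <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
  (f - mean(f)) / stats::sd(f)
}

#' Grassland type levels used throughout the package
#'
#' @return character vector: alpine meadow, alpine steppe, alpine desert
#'   steppe (the order used for integer-coded type rasters).
#' @export
grassland_levels <- function() {
  c("alpine_meadow", "alpine_steppe", "alpine_desert_steppe")
}

#' Generate a synthetic landscape with known grazing truth
#'
#' Produces a self-contained test landscape: a contiguous Voronoi county
#' mosaic, autocorrelated covariate fields, a per-year pixel truth density
#' that is a documented monotone function of the first three covariates, an
#' observed/potential NDVI pair whose deficit increases with density, and a
#' census table obtained by zonal summation of the truth (so census/truth
#' consistency holds by construction).
#'
#' @param config a [landscape_config()].
#' @return object of class `synthetic_truth`: list with elements
#'   `truth_density` (list of matrices, one per year, SU/pixel),
#'   `covariates` (named list of matrices), `ndvi_observed`/`ndvi_potential`
#'   (lists of matrices, one per year), `county_zones` (integer matrix),
#'   `grassland_type` (integer matrix coded by [grassland_levels()]),
#'   `census` (a [census_table()]), and `config`.
#' @examples
#' truth <- generate_landscape(landscape_config(grid_rows = 20, grid_cols = 20,
#'                                              n_counties = 5, seed = 1))
#' range(truth$county_zones)
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  nr <- config$grid_rows; nc <- config$grid_cols
  n_pixels <- nr * nc

  # Voronoi county mosaic: nearest of n_counties seed pixels (ties -> lower id)
  seeds <- sample.int(n_pixels, config$n_counties)
  seed_rc <- cbind((seeds - 1L) %% nr + 1L, (seeds - 1L) %/% nr + 1L)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  best_d2 <- matrix(Inf, nr, nc)
  zones <- matrix(NA_integer_, nr, nc)
  for (j in seq_len(config$n_counties)) {
    d2 <- (rows - seed_rc[j, 1L])^2 + (cols - seed_rc[j, 2L])^2
    upd <- d2 < best_d2
    zones[upd] <- j
    best_d2[upd] <- d2[upd]
  }

  covariates <- lapply(seq_len(config$n_covariates), function(i)
    autocorrelated_field(nr, nc, config$spatial_range))
  names(covariates) <- paste0("cov", seq_len(config$n_covariates))

  type_field <- autocorrelated_field(nr, nc, config$spatial_range)
  breaks <- stats::quantile(type_field, c(1 / 3, 2 / 3))
  grassland_type <- matrix(1L, nr, nc)       # high field -> meadow
  grassland_type[type_field <= breaks[2L]] <- 2L
  grassland_type[type_field <= breaks[1L]] <- 3L

  b <- config$density_coef
  base <- exp(b[["intercept"]] + b[["c1"]] * covariates$cov1 +
                b[["c2"]] * covariates$cov2 + b[["c3"]] * covariates$cov3 +
                b[["c1c2"]] * covariates$cov1 * covariates$cov2)

  deficit <- function(d)
    config$ndvi_deficit_scale * d / (config$ndvi_deficit_halfsat + d)

  pot_base <- 0.65 + 0.2 * autocorrelated_field(nr, nc, config$spatial_range)
  pot_base <- pmin(pmax(pot_base, 0.4), 0.95)
  ndvi_noise_sd <- 0.01 * config$noise_sd

  truth_density <- vector("list", config$n_years)
  ndvi_observed <- vector("list", config$n_years)
  ndvi_potential <- vector("list", config$n_years)
  census_rows <- vector("list", config$n_years)
  for (t in seq_len(config$n_years)) {
    scale_t <- 1 + config$year_trend * (t - 1L)
    noise <- if (config$noise_sd > 0)
      matrix(stats::rnorm(n_pixels, sd = config$noise_sd), nr, nc)
    else matrix(0, nr, nc)
    truth <- pmax(scale_t * base + noise, 0)
    obs_noise <- if (ndvi_noise_sd > 0)
      matrix(stats::rnorm(n_pixels, sd = ndvi_noise_sd), nr, nc)
    else matrix(0, nr, nc)
    obs <- pot_base - deficit(truth) + obs_noise
    # grazing never lifts observed NDVI above potential
    grazed <- truth > 0
    obs[grazed] <- pmin(obs[grazed], pot_base[grazed])
    obs <- pmax(obs, -1)
    truth_density[[t]] <- truth
    ndvi_potential[[t]] <- pot_base
    ndvi_observed[[t]] <- obs
    sums <- zonal_sum(truth, zones)
    census_rows[[t]] <- data.frame(
      county_id = as.integer(names(sums)),
      year = t,
      su_total = as.numeric(sums),
      provenance = "recorded",
      stringsAsFactors = FALSE
    )
  }

  census <- census_table(do.call(rbind, census_rows))
  structure(
    list(
      truth_density = truth_density,
      covariates = covariates,
      ndvi_observed = ndvi_observed,
      ndvi_potential = ndvi_potential,
      county_zones = zones,
      grassland_type = grassland_type,
      census = census,
      config = config
    ),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Synthetic grazing landscape: %dx%d pixels, %d counties, %d year(s)\n",
    cfg$grid_rows, cfg$grid_cols, cfg$n_counties, cfg$n_years))
  cat(sprintf("  covariates: %d; noise sd %.3g SU/pixel; seed %d\n",
              cfg$n_covariates, cfg$noise_sd, cfg$seed))
  cat(sprintf("  total census SU (year 1): %.1f\n",
              sum(x$census$su_total[x$census$year == 1])))
  invisible(x)
}

#' Write a synthetic landscape to a directory of plain-text files
#'
#' Rasters go to ESRI ASCII grids (one file per variable/year), the census to
#' CSV; a `landscape.yaml` records the generating configuration.
#'
#' @param truth a `synthetic_truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(truth, dir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(truth$covariates))
    write_ascii_grid(truth$covariates[[nm]], file.path(dir, paste0(nm, ".asc")))
  write_ascii_grid(truth$county_zones, file.path(dir, "county_zones.asc"))
  write_ascii_grid(truth$grassland_type, file.path(dir, "grassland_type.asc"))
  for (t in seq_along(truth$truth_density)) {
    write_ascii_grid(truth$truth_density[[t]],
                     file.path(dir, sprintf("truth_density_y%02d.asc", t)))
    write_ascii_grid(truth$ndvi_observed[[t]],
                     file.path(dir, sprintf("ndvi_observed_y%02d.asc", t)))
    write_ascii_grid(truth$ndvi_potential[[t]],
                     file.path(dir, sprintf("ndvi_potential_y%02d.asc", t)))
  }
  write_census_csv(truth$census, file.path(dir, "census.csv"))
  if (requireNamespace("yaml", quietly = TRUE)) {
    cfg <- unclass(truth$config)
    cfg$density_coef <- as.list(cfg$density_coef)
    writeLines(yaml::as.yaml(cfg), file.path(dir, "landscape.yaml"))
  }
  invisible(dir)
}
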