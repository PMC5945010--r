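#' Specify the coupling between greenness and a synthetic NDVI grid
#'
#' The synthetic satellite product assumes NDVI is linearly coupled to the
#' park's true monthly mean greenness, plus independent per-cell noise:
#' `ndvi(cell, m) = clip(intercept + slope * mu(m) + Normal(0, cell_noise_sd), -1, 1)`.
#' Cells are laid out on a regular lat/lon lattice centered on the park.
#'
#' @param park_center numeric `c(lat, lon)` in decimal degrees.
#' @param intercept,slope linear coupling coefficients (NDVI units; slope
#'   per greenness unit). NDVI and the greenness index are different
#'   quantities, so the slope need not be near 1.
#' @param cell_noise_sd per-cell Gaussian noise (NDVI units). The default
#'   0.30, averaged over the 81 cells within 0.5 degrees of the center of
#'   an 0.1-degree grid, attenuates the pooled greenness-NDVI correlation
#'   of the default scenario to about 0.6.
#' @param grid_extent_deg full width/height of the lattice in degrees.
#' @param grid_step_deg lattice spacing in degrees; must be positive.
#' @return an object of class `ndvi_coupling_spec`.
#' @export
ndvi_coupling_spec <- function(park_center,
                               intercept = 0.05,
                               slope = 1,
                               cell_noise_sd = 0.30,
                               grid_extent_deg = 1.0,
                               grid_step_deg = 0.1) {
  stopifnot(length(park_center) == 2, is.numeric(park_center),
            grid_step_deg > 0, grid_extent_deg >= 0, cell_noise_sd >= 0)
  structure(
    list(park_center = as.numeric(park_center),
         intercept = intercept, slope = slope,
         cell_noise_sd = cell_noise_sd,
         grid_extent_deg = grid_extent_deg,
         grid_step_deg = grid_step_deg),
    class = "ndvi_coupling_spec"
  )
}

#' Generate a synthetic monthly NDVI grid around a park
#'
#' Evaluates the linear greenness-NDVI coupling of an [ndvi_coupling_spec()]
#' at every lattice cell and calendar month, adds per-cell noise, and clips
#' values to the NDVI range `[-1, 1]`.
#'
#' @param spec an [ndvi_coupling_spec()].
#' @param profile a [seasonal_profile()] providing the true monthly means.
#' @param seed integer seed; generation is reproducible.
#' @return a data.frame with columns `lat`, `lon`, `month`, `ndvi` (one row
#'   per cell-month).
#' @export
generate_ndvi_grid <- function(spec, profile, seed = 1L) {
  stopifnot(inherits(spec, "ndvi_coupling_spec"),
            inherits(profile, "seasonal_profile"))
  half <- spec$grid_extent_deg / 2
  offs <- seq(-half, half, by = spec$grid_step_deg)
  lat <- spec$park_center[1] + offs
  lon <- spec$park_center[2] + offs
  cells <- expand.grid(lat = lat, lon = lon, month = 1:12,
                       KEEP.OUT.ATTRS = FALSE)
  mu <- profile$month_means[cells$month]
  noise <- withr::with_seed(as.integer(seed), {
    stats::rnorm(nrow(cells), 0, spec$cell_noise_sd)
  })
  cells$ndvi <- pmin(pmax(spec$intercept + spec$slope * mu + noise, -1), 1)
  cells
}

#' Read or write the NDVI grid CSV dialect
#'
#' The grid is stored as a plain CSV with header `lat,lon,month,ndvi`
#' (decimal degrees, calendar month 1-12, NDVI in `[-1, 1]`).
#'
#' @param path CSV path.
#' @return `load_ndvi_grid` returns the grid data.frame.
#' @export
load_ndvi_grid <- function(path) {
  if (!file.exists(path)) stop("NDVI grid not found: ", path)
  grid <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("lat", "lon", "month", "ndvi")
  if (!all(required %in% names(grid))) {
    stop("NDVI grid must have columns lat, lon, month, ndvi")
  }
  if (any(grid$month < 1 | grid$month > 12)) stop("month outside 1-12")
  if (any(abs(grid$ndvi) > 1)) stop("ndvi outside [-1, 1]")
  grid[required]
}

#' @rdname load_ndvi_grid
#' @param grid an NDVI grid data.frame.
#' @export
write_ndvi_grid <- function(grid, path) {
  utils::write.csv(grid[, c("lat", "lon", "month", "ndvi")], path,
                   row.names = FALSE)
  invisible(path)
}
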