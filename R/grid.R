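#' Define the model grid
#'
#' The model domain is a regular lat-lon box of square cells with a small
#' number of vertical air levels and annual time steps. The desk-scale
#' default (20 x 24 cells of 1e4 km2, 4 levels, 1980-2009) is deliberately
#' much coarser than an operational quarter-degree transport grid; every
#' dimension is configurable so finer resolutions remain possible.
#'
#' @param n_lat,n_lon number of grid rows (south to north) and columns
#'   (west to east).
#' @param cell_area_km2 area of one cell (km2); cells are treated as square.
#' @param n_levels number of vertical air levels.
#' @param years contiguous, strictly increasing calendar years simulated.
#' @param level_thickness_m thickness of each air level (m), length
#'   `n_levels`.
#' @param land_fraction,water_fraction fraction of each cell surface that is
#'   soil-covered land and open fresh water; they need not sum to 1 (the
#'   remainder is sealed surface receiving no deposition bookkeeping).
#' @param water_depth_m mean depth of the surface-water compartment (m).
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_lat = 20, n_lon = 24, cell_area_km2 = 1e4,
                      n_levels = 4, years = 1980:2009,
                      level_thickness_m = default_level_thickness(n_levels),
                      land_fraction = 0.9, water_fraction = 0.08,
                      water_depth_m = 5) {
  stopifnot(n_lat >= 1, n_lon >= 1, n_levels >= 1, cell_area_km2 > 0)
  years <- as.integer(years)
  if (length(years) < 1 || any(diff(years) != 1L)) {
    stop("`years` must be strictly increasing and contiguous")
  }
  if (length(level_thickness_m) != n_levels || any(level_thickness_m <= 0)) {
    stop("`level_thickness_m` must have one positive entry per level")
  }
  if (land_fraction < 0 || water_fraction < 0 ||
      land_fraction + water_fraction > 1) {
    stop("land and water fractions must be nonnegative and sum to at most 1")
  }
  structure(list(
    n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
    cell_area_km2 = cell_area_km2,
    cell_area_m2 = cell_area_km2 * 1e6,
    dx_m = sqrt(cell_area_km2) * 1e3,
    n_levels = as.integer(n_levels),
    level_thickness_m = level_thickness_m,
    years = years, n_years = length(years),
    land_fraction = land_fraction,
    water_fraction = water_fraction,
    water_depth_m = water_depth_m
  ), class = "grid_spec")
}

# Near-surface levels thin, upper levels thick, as in layered transport
# models; truncated/extended geometrically for non-default level counts.
default_level_thickness <- function(n_levels) {
  base <- c(100, 400, 1500, 3000)
  if (n_levels <= 4) return(base[seq_len(n_levels)])
  c(base, rep(3000, n_levels - 4))
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells (%.0f km2 each), %d levels, %d-%d\n",
              x$n_lat, x$n_lon, x$cell_area_km2, x$n_levels,
              x$years[1], x$years[x$n_years]))
  invisible(x)
}

#' Number of horizontal cells in a grid
#' @param grid a [grid_spec()].
#' @return integer cell count.
#' @export
n_cells <- function(grid) grid$n_lat * grid$n_lon
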