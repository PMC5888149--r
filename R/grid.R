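#' Define the analysis grid
#'
#' The analysis unit is a square grid of cells (quarter-degree cells in the
#' continental application; 0.5 degree by default here), each subdivided into
#' `pixels_per_cell` x `pixels_per_cell` burn-raster pixels. Cell polygons are
#' half-open `[west, east) x [south, north)` so cells tile without double
#' counting; `cell_id` runs row-major from the north-west origin. Distances
#' are planar: one degree corresponds to `km_per_deg` km, and pixel area in
#' km^2 is carried explicitly so no geodesy is needed.
#'
#' @param n_rows,n_cols grid dimensions in cells (each at least 5; the
#'   spatial model's adjacency needs neighbours).
#' @param cell_deg cell size in degrees.
#' @param origin_lon,origin_lat longitude of the west edge and latitude of
#'   the north edge.
#' @param pixels_per_cell burn-raster pixels per cell side.
#' @param km_per_deg planar km per degree.
#' @return an object of class `pd_grid`.
#' @export
pd_grid <- function(n_rows = 20, n_cols = 20, cell_deg = 0.5,
                    origin_lon = 20, origin_lat = 0,
                    pixels_per_cell = 10, km_per_deg = 111.32) {
  if (n_rows < 5 || n_cols < 5) {
    abort("grid must be at least 5 x 5 cells: model adjacency needs neighbours")
  }
  pixel_deg <- cell_deg / pixels_per_cell
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      cell_deg = cell_deg, origin_lon = origin_lon, origin_lat = origin_lat,
      pixels_per_cell = as.integer(pixels_per_cell),
      pixel_deg = pixel_deg, km_per_deg = km_per_deg,
      pixel_area_km2 = (pixel_deg * km_per_deg)^2,
      px_rows = as.integer(n_rows * pixels_per_cell),
      px_cols = as.integer(n_cols * pixels_per_cell)
    ),
    class = "pd_grid"
  )
}

#' @export
print.pd_grid <- function(x, ...) {
  cat(sprintf(
    "<pd_grid> %d x %d cells of %g deg (%d x %d pixels, %.2f km2/pixel)\n",
    x$n_rows, x$n_cols, x$cell_deg, x$px_rows, x$px_cols, x$pixel_area_km2
  ))
  invisible(x)
}

#' Cell table for a grid
#'
#' One row per cell with bounds and centre coordinates.
#'
#' @param grid a [pd_grid()].
#' @return a tibble with `cell_id`, `cell_row`, `cell_col`, bounds and centre.
#' @export
grid_cells <- function(grid) {
  rows <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  cols <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  lon_min <- grid$origin_lon + (cols - 1) * grid$cell_deg
  lat_max <- grid$origin_lat - (rows - 1) * grid$cell_deg
  tibble(
    cell_id = seq_along(rows),
    cell_row = rows, cell_col = cols,
    lon_min = lon_min, lon_max = lon_min + grid$cell_deg,
    lat_min = lat_max - grid$cell_deg, lat_max = lat_max,
    lon_c = lon_min + grid$cell_deg / 2,
    lat_c = lat_max - grid$cell_deg / 2
  )
}

# cell_id containing a lon/lat point (half-open cells); NA outside the grid
cell_of_lonlat <- function(grid, lon, lat) {
  col <- floor((lon - grid$origin_lon) / grid$cell_deg) + 1
  row <- floor((grid$origin_lat - lat) / grid$cell_deg) + 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  out <- (row - 1) * grid$n_cols + col
  out[!ok] <- NA_integer_
  as.integer(out)
}

# pixel-centre coordinates (pixel row 1 = north edge)
pixel_lon <- function(grid, pcol) grid$origin_lon + (pcol - 0.5) * grid$pixel_deg
pixel_lat <- function(grid, prow) grid$origin_lat - (prow - 0.5) * grid$pixel_deg

# pixel indices of a lon/lat point
pixel_of_lonlat <- function(grid, lon, lat) {
  pcol <- floor((lon - grid$origin_lon) / grid$pixel_deg) + 1
  prow <- floor((grid$origin_lat - lat) / grid$pixel_deg) + 1
  list(prow = as.integer(prow), pcol = as.integer(pcol))
}

# cell containing a pixel
cell_of_pixel <- function(grid, prow, pcol) {
  crow <- (prow - 1L) %/% grid$pixels_per_cell + 1L
  ccol <- (pcol - 1L) %/% grid$pixels_per_cell + 1L
  (crow - 1L) * grid$n_cols + ccol
}
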