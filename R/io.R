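#' Read and write rasters as Esri ASCII grids
#'
#' Pixel rasters (burn dates, elevation, NPP, pyrodiversity surfaces) are
#' stored as plain-text Esri ASCII grids (`.asc`): a six-line header followed
#' by rows of values from north to south. Integer rasters use -1 as nodata by
#' default (unburned pixels); float rasters use -9999.
#'
#' @param m numeric matrix, row 1 = northernmost row.
#' @param path file path.
#' @param grid a [pd_grid()] supplying the geotransform.
#' @param nodata nodata sentinel written in place of `NA`.
#' @return `read_ascii_grid()` returns a list with `matrix` and the header
#'   fields; `write_ascii_grid()` returns `path` invisibly.
#' @export
write_ascii_grid <- function(m, path, grid, nodata = -1) {
  stopifnot(nrow(m) == grid$px_rows, ncol(m) == grid$px_cols)
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", grid$origin_lon),
    sprintf("yllcorner %.10g", grid$origin_lat - nrow(m) * grid$pixel_deg),
    sprintf("cellsize %.10g", grid$pixel_deg),
    sprintf("NODATA_value %.10g", nodata)
  )
  mm <- m
  mm[is.na(mm)] <- nodata
  body <- apply(mm, 1, function(r) paste(format(r, trim = TRUE, digits = 12),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- strsplit(hdr, "\\s+")
  vals <- setNames(vapply(kv, function(x) as.numeric(x[2]), 0),
                   tolower(vapply(kv, `[`, "", 1)))
  body <- lines[-(1:6)]
  m <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  m[m == vals[["nodata_value"]]] <- NA
  list(matrix = m, ncols = vals[["ncols"]], nrows = vals[["nrows"]],
       xllcorner = vals[["xllcorner"]], yllcorner = vals[["yllcorner"]],
       cellsize = vals[["cellsize"]], nodata = vals[["nodata_value"]])
}

#' Read and write polygon tables as GeoJSON
#'
#' Polygon tables (protected areas, species ranges) are tibbles with columns
#' `poly_id`, `x`, `y` (one closed ring per id) plus optional per-polygon
#' properties supplied separately.
#'
#' @param polys polygon tibble.
#' @param path file path.
#' @param properties optional tibble of per-polygon properties with a
#'   `poly_id` column.
#' @return `read_polygons_geojson()` returns a list with `polys` and
#'   `properties` tibbles.
#' @export
write_polygons_geojson <- function(polys, path, properties = NULL) {
  rings <- polys_to_rings(polys)
  feats <- lapply(names(rings), function(id) {
    ring <- rings[[id]]
    ring <- rbind(ring, ring[1, , drop = FALSE])  # close the ring
    props <- list(poly_id = id)
    if (!is.null(properties)) {
      row <- properties[properties$poly_id == id, , drop = FALSE]
      if (nrow(row) == 1) props <- c(props, as.list(row[setdiff(names(row), "poly_id")]))
    }
    list(
      type = "Feature",
      properties = props,
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2])))
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygons_geojson
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  polys <- list(); props <- list()
  for (f in gj$features) {
    id <- f$properties$poly_id
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    ring <- ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
    polys[[id]] <- tibble(poly_id = id, x = ring[, 1], y = ring[, 2])
    props[[id]] <- as_tibble(f$properties)
  }
  list(polys = bind_rows(polys), properties = bind_rows(props))
}

#' Write and read the burn history
#'
#' One ASCII grid per year layer (`burn_year<k>.asc`, int days since
#' 2000-01-01, nodata -1) in a directory.
#'
#' @param burn a `pd_burn` object (see [gen_fire_history()]).
#' @param dir output directory (created if missing).
#' @param grid the [pd_grid()] the layers belong to (for reading).
#' @return `read_burn_history()` returns a `pd_burn` object.
#' @export
write_burn_history <- function(burn, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (k in seq_along(burn$layers)) {
    write_ascii_grid(burn$layers[[k]],
                     file.path(dir, sprintf("burn_year%02d.asc", k)),
                     burn$grid, nodata = -1)
  }
  invisible(dir)
}

#' @rdname write_burn_history
#' @export
read_burn_history <- function(dir, grid) {
  files <- sort(list.files(dir, pattern = "^burn_year\\d+\\.asc$",
                           full.names = TRUE))
  layers <- lapply(files, function(f) {
    m <- read_ascii_grid(f)$matrix
    storage.mode(m) <- "integer"
    m
  })
  structure(list(grid = grid, layers = layers), class = "pd_burn")
}
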