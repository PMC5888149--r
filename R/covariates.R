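#' Summarise monthly rainfall climatology per cell
#'
#' Mean annual precipitation is the sum of the 12 monthly means; the peak
#' rain month is the argmax, with ties resolved to the earliest month.
#'
#' @param monthly_rain cells x 12 matrix (mm/month), or a single 12-vector.
#' @return tibble with `map_mm` and `peak_month`.
#' @export
summarise_climate <- function(monthly_rain) {
  if (is.null(dim(monthly_rain))) monthly_rain <- matrix(monthly_rain, nrow = 1)
  stopifnot(ncol(monthly_rain) == 12)
  tibble(
    map_mm = rowSums(monthly_rain),
    peak_month = apply(monthly_rain, 1, which.max)  # which.max: earliest on ties
  )
}

# aggregate a pixel matrix to cells: returns a per-cell vector (cell_id order)
cell_aggregate <- function(grid, m, fun = c("mean", "sd")) {
  fun <- match.arg(fun)
  pr <- rep(seq_len(grid$px_rows), times = grid$px_cols)
  pc <- rep(seq_len(grid$px_cols), each = grid$px_rows)
  cid <- cell_of_pixel(grid, pr, pc)
  v <- as.vector(m)
  f <- if (fun == "mean") function(x) mean(x, na.rm = TRUE) else
    function(x) stats::sd(x, na.rm = TRUE)
  out <- tapply(v, cid, f)[as.character(seq_len(grid$n_rows * grid$n_cols))]
  as.numeric(out)
}

#' Multi-year mean NPP per cell
#'
#' Stacks the annual NPP rasters, averages across years per pixel, then
#' averages pixels within each cell; missing pixels are excluded. For
#' complete data the order of averaging is immaterial.
#'
#' @param npp_stack list of pixel matrices (kg C m^-2 yr^-1), one per year.
#' @param grid the [pd_grid()].
#' @return numeric vector of cell means in `cell_id` order.
#' @export
mean_npp <- function(npp_stack, grid) {
  s <- Reduce(function(a, b) {
    a$sum <- a$sum + ifelse(is.na(b), 0, b)
    a$n <- a$n + !is.na(b)
    a
  }, npp_stack, list(sum = matrix(0, grid$px_rows, grid$px_cols),
                     n = matrix(0, grid$px_rows, grid$px_cols)))
  px_mean <- s$sum / ifelse(s$n == 0, NA, s$n)
  unname(cell_aggregate(grid, px_mean, "mean"))
}

#' Topographic heterogeneity per cell
#'
#' Standard deviation of pixel elevations within each cell (m).
#'
#' @param elevation pixel elevation matrix (m).
#' @param grid the [pd_grid()].
#' @return numeric vector in `cell_id` order.
#' @export
topo_heterogeneity <- function(elevation, grid) {
  unname(cell_aggregate(grid, elevation, "sd"))
}

#' Protected-area coverage fraction per cell
#'
#' Fraction of each cell's area intersected by the union of the protected
#' area polygons (which the generator guarantees disjoint, so the union is a
#' sum of pairwise intersections).
#'
#' @param cells cell table from [grid_cells()].
#' @param pa_polys polygon tibble (`poly_id`, `x`, `y`).
#' @return numeric vector of fractions in `[0, 1]`, `cell_id` order.
#' @export
pa_coverage <- function(cells, pa_polys) {
  rings <- polys_to_rings(pa_polys)
  cell_area <- (cells$lon_max - cells$lon_min) * (cells$lat_max - cells$lat_min)
  frac <- numeric(nrow(cells))
  for (ring in rings) {
    bx <- range(ring[, 1]); by <- range(ring[, 2])
    cand <- which(cells$lon_min < bx[2] & cells$lon_max > bx[1] &
                    cells$lat_min < by[2] & cells$lat_max > by[1])
    for (i in cand) {
      frac[i] <- frac[i] + ring_rect_intersection_area(
        ring, cells$lon_min[i], cells$lon_max[i],
        cells$lat_min[i], cells$lat_max[i]) / cell_area[i]
    }
  }
  pmin(frac, 1)
}

#' Rasterise species ranges to per-cell richness
#'
#' A species is present in a cell when its range polygon intersects the cell
#' polygon with positive area; richness is the count of present species.
#'
#' @param range_polys polygon tibble (`poly_id` = species id, `x`, `y`).
#' @param cells cell table from [grid_cells()].
#' @return list with `richness` (integer vector, `cell_id` order) and
#'   `presence` (cells x species logical matrix, columns named by species).
#' @export
rasterise_richness <- function(range_polys, cells) {
  rings <- polys_to_rings(range_polys)
  pres <- matrix(FALSE, nrow(cells), length(rings),
                 dimnames = list(NULL, names(rings)))
  for (k in seq_along(rings)) {
    ring <- rings[[k]]
    bx <- range(ring[, 1]); by <- range(ring[, 2])
    cand <- which(cells$lon_min < bx[2] & cells$lon_max > bx[1] &
                    cells$lat_min < by[2] & cells$lat_max > by[1])
    for (i in cand) {
      a <- ring_rect_intersection_area(ring, cells$lon_min[i], cells$lon_max[i],
                                       cells$lat_min[i], cells$lat_max[i])
      if (a > 1e-12) pres[i, k] <- TRUE
    }
  }
  list(richness = as.integer(rowSums(pres)), presence = pres)
}

#' Partition species into trait-based groups
#'
#' Mammals are partitioned into bats (by flag), mammals excluding bats, small
#' (body mass at or below the median: ties inclusive-low), large (the
#' complement) and common (range size at or above the median: ties
#' inclusive-high). Birds are partitioned into all and common only. Medians
#' are computed on the species pool passed in (clip ranges to the savanna
#' grid first).
#'
#' @param traits tibble with `species_id`, `taxon` ("mammal"/"bird"),
#'   `body_mass_kg`, `is_bat`, `range_size_cells`.
#' @return `traits` with logical columns `grp_small`, `grp_large`,
#'   `grp_common` (mass/commonness medians computed within taxon).
#' @export
partition_species <- function(traits) {
  traits %>%
    group_by(.data$taxon) %>%
    mutate(
      grp_small = .data$taxon == "mammal" &
        .data$body_mass_kg <= median(.data$body_mass_kg),
      grp_large = .data$taxon == "mammal" & !.data$grp_small,
      grp_common = .data$range_size_cells >= median(.data$range_size_cells)
    ) %>%
    ungroup()
}

#' Assemble the per-cell analysis table
#'
#' Joins everything the richness models need: climate summaries (MAP, peak
#' month), multi-year mean NPP, topographic heterogeneity, protected-area
#' coverage, the savanna mask (MAP >= 300 mm unless a mask is supplied), the
#' wet/dry classification (MAP > 650 mm), the analysis flag (savanna cells
#' with PA coverage >= `pa_threshold`), per-group richness from rasterised
#' ranges, and the per-cell fire summaries.
#'
#' @param env a [gen_environment()] stack.
#' @param cell_fires optional [cell_summaries()] output.
#' @param pa_polys optional protected-area polygons.
#' @param range_polys,traits optional species ranges and trait table.
#' @param richness optional tibble of pre-computed richness columns (joined
#'   by `cell_id`; used when richness is generated directly).
#' @param savanna_min_map savanna rainfall floor, mm/yr.
#' @param wet_threshold wet/dry savanna split, mm/yr.
#' @param pa_threshold minimum PA coverage for a cell to enter the analysis.
#' @param savanna_mask optional logical vector overriding the rainfall-floor
#'   savanna mask.
#' @return tibble, one row per cell.
#' @export
build_cell_table <- function(env, cell_fires = NULL, pa_polys = NULL,
                             range_polys = NULL, traits = NULL,
                             richness = NULL,
                             savanna_min_map = 300, wet_threshold = 650,
                             pa_threshold = 0.5, savanna_mask = NULL) {
  stopifnot(inherits(env, "pd_env"))
  grid <- env$grid
  cells <- env$cells
  clim <- summarise_climate(env$monthly_rain)
  cells$map_mm <- clim$map_mm
  cells$peak_month <- clim$peak_month
  cells$npp <- mean_npp(env$npp, grid)
  cells$topo_het <- topo_heterogeneity(env$elevation, grid)
  cells$pa_fraction <- if (is.null(pa_polys) || nrow(pa_polys) == 0) 0 else
    pa_coverage(cells, pa_polys)
  cells$is_savanna <- savanna_mask %||% (cells$map_mm >= savanna_min_map)
  cells$is_wet <- cells$map_mm > wet_threshold
  cells$in_analysis <- cells$is_savanna & cells$pa_fraction >= pa_threshold

  if (!is.null(range_polys) && !is.null(traits)) {
    ras <- rasterise_richness(range_polys, cells)
    pres <- ras$presence[, traits$species_id, drop = FALSE]
    # range size on the savanna species pool, clipped to the grid
    traits$range_size_cells <- colSums(pres & cells$is_savanna)
    traits <- partition_species(traits)
    grp_count <- function(sel) as.integer(rowSums(pres[, sel, drop = FALSE]))
    mam <- traits$taxon == "mammal"; brd <- traits$taxon == "bird"
    cells$richness_mammals_all <- grp_count(mam)
    cells$richness_mammals_nobats <- grp_count(mam & !traits$is_bat)
    cells$richness_bats <- grp_count(mam & traits$is_bat)
    cells$richness_mammals_small <- grp_count(mam & traits$grp_small)
    cells$richness_mammals_large <- grp_count(mam & traits$grp_large)
    cells$richness_mammals_common <- grp_count(mam & traits$grp_common)
    cells$richness_birds_all <- grp_count(brd)
    cells$richness_birds_common <- grp_count(brd & traits$grp_common)
  }
  if (!is.null(richness)) cells <- left_join(cells, richness, by = "cell_id")
  if (!is.null(cell_fires)) cells <- left_join(cells, cell_fires, by = "cell_id")
  cells
}
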