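#' Generate a synthetic savanna environment
#'
#' Builds the full environmental input stack for the pipeline on a planar
#' grid: a smooth mean-annual-precipitation (MAP) surface spanning
#' `map_range` mm across cells (Gaussian random field, rescaled), a spatially
#' varying peak rainfall month with a wrapped-cosine monthly profile, a pixel
#' elevation raster whose within-cell roughness varies smoothly in space (so
#' topographic heterogeneity is a usable covariate), and annual net primary
#' productivity (NPP) rasters generated as a saturating monotone function of
#' MAP plus noise, so NPP and rainfall are positively rank-correlated by
#' construction.
#'
#' @param grid a [pd_grid()] of at least 5 x 5 cells.
#' @param seed integer seed; the stack is a deterministic function of
#'   `(grid, seed, parameters)`.
#' @param map_range MAP range (mm/yr) spanned exactly across cells.
#' @param n_years_npp number of annual NPP layers.
#' @param rain_concentration wrapped-cosine concentration of the monthly
#'   rainfall profile (larger = peakier wet season).
#' @return an object of class `pd_env`: list with `grid`, `cells` (tibble
#'   with `cell_id`, bounds, `map_mm`, `peak_month`), `monthly_rain`
#'   (cells x 12, mm/month), `elevation` (pixel matrix, m) and `npp` (list of
#'   pixel matrices, kg C m^-2 yr^-1).
#' @export
gen_environment <- function(grid, seed, map_range = c(300, 1400),
                            n_years_npp = 5, rain_concentration = 2) {
  stopifnot(inherits(grid, "pd_grid"))
  with_seed(derive_seed(seed, "environment"), {
    cells <- grid_cells(grid)
    nr <- grid$n_rows; nc <- grid$n_cols

    # rank-uniform marginal: spans map_range exactly and keeps the wet/dry
    # strata reasonably balanced while preserving the field's smoothness
    f_map <- gaussian_field(nr, nc, range_cells = max(3, nr / 6))
    map_cell <- f_map
    map_cell[] <- map_range[1] + (rank(f_map) - 1) / (length(f_map) - 1) *
      diff(map_range)

    # peak rain month drifts smoothly across the map
    f_peak <- gaussian_field(nr, nc, range_cells = max(3, nr / 4))
    peak_cell <- 1L + as.integer(floor(stats::pnorm(f_peak) * 12)) %% 12L

    # row-major (cell_id) ordering: t() because cells run west-east first
    map_v <- as.vector(t(map_cell))
    peak_v <- as.vector(t(peak_cell))

    months <- 1:12
    monthly_rain <- t(vapply(seq_len(nrow(cells)), function(i) {
      w <- exp(rain_concentration * cos(2 * pi * (months - peak_v[i]) / 12))
      map_v[i] * w / sum(w)
    }, numeric(12)))

    # elevation: smooth cell-level base + pixel roughness with smooth SD
    f_base <- gaussian_field(nr, nc, range_cells = max(3, nr / 5))
    f_rough <- gaussian_field(nr, nc, range_cells = max(3, nr / 5))
    sd_cell <- 10 + 120 * stats::pnorm(f_rough)
    ppc <- grid$pixels_per_cell
    up <- function(m) m[rep(seq_len(nr), each = ppc), rep(seq_len(nc), each = ppc)]
    elevation <- 600 + 350 * up(f_base) +
      matrix(rnorm(grid$px_rows * grid$px_cols), grid$px_rows) * up(sd_cell)

    # NPP: saturating monotone in MAP + interannual and pixel noise
    npp_base <- 0.1 + 1.3 * (up(map_cell) / max(map_range))^1.2
    npp <- lapply(seq_len(n_years_npp), function(y) {
      yr_eff <- 1 + 0.08 * rnorm(1)
      pmax(0.01, npp_base * yr_eff +
             0.05 * matrix(rnorm(grid$px_rows * grid$px_cols), grid$px_rows))
    })

    cells$map_mm <- map_v
    cells$peak_month <- peak_v
    structure(
      list(grid = grid, cells = cells, monthly_rain = monthly_rain,
           elevation = elevation, npp = npp,
           params = list(seed = seed, map_range = map_range,
                         n_years_npp = n_years_npp,
                         rain_concentration = rain_concentration)),
      class = "pd_env"
    )
  })
}

#' @export
print.pd_env <- function(x, ...) {
  cat(sprintf("<pd_env> %d cells; MAP %.0f-%.0f mm; %d NPP years\n",
              nrow(x$cells), min(x$cells$map_mm), max(x$cells$map_mm),
              length(x$npp)))
  invisible(x)
}
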