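#' Generate protected-area polygons
#'
#' Places `n_pa` pairwise-disjoint rectangular protected areas, each spanning
#' more than one cell, with combined coverage below half the grid. Placement
#' is by rejection sampling with a separation margin; if the requested count
#' cannot be packed, fewer are returned with a warning.
#'
#' @param env a [gen_environment()] stack.
#' @param n_pa number of protected areas requested.
#' @param size_cells range of PA side lengths, in cells.
#' @param seed integer seed.
#' @return polygon tibble (`poly_id` = `pa_01`, ..., `x`, `y`); empty when
#'   `n_pa = 0`.
#' @export
gen_protected_areas <- function(env, n_pa = 8, size_cells = c(2, 4), seed = 1) {
  stopifnot(inherits(env, "pd_env"))
  grid <- env$grid
  empty <- tibble(poly_id = character(0), x = numeric(0), y = numeric(0))
  if (n_pa == 0) return(empty)
  with_seed(derive_seed(seed, "protected_areas"), {
    lon0 <- grid$origin_lon; lat0 <- grid$origin_lat
    W <- grid$n_cols * grid$cell_deg; H <- grid$n_rows * grid$cell_deg
    total_area <- W * H
    placed <- list()
    used_area <- 0
    tries <- 0
    while (length(placed) < n_pa && tries < 2000) {
      tries <- tries + 1
      w <- runif(1, size_cells[1], size_cells[2]) * grid$cell_deg
      h <- runif(1, size_cells[1], size_cells[2]) * grid$cell_deg
      if (used_area + w * h > 0.45 * total_area) break
      x0 <- lon0 + runif(1, 0, W - w)
      y0 <- lat0 - H + runif(1, 0, H - h)
      margin <- 0.5 * grid$cell_deg
      clash <- any(vapply(placed, function(p)
        x0 < p$x1 + margin && x0 + w > p$x0 - margin &&
          y0 < p$y1 + margin && y0 + h > p$y0 - margin, logical(1)))
      if (clash) next
      placed[[length(placed) + 1]] <- list(x0 = x0, x1 = x0 + w,
                                           y0 = y0, y1 = y0 + h)
      used_area <- used_area + w * h
    }
    if (length(placed) < n_pa) {
      warn(sprintf("placed %d of %d requested protected areas (packing limit)",
                   length(placed), n_pa))
    }
    if (length(placed) == 0) return(empty)
    purrr::map_dfr(seq_along(placed), function(i) {
      p <- placed[[i]]
      r <- rect_ring(p$x0, p$x1, p$y0, p$y1)
      tibble(poly_id = sprintf("pa_%02d", i), x = r[, 1], y = r[, 2])
    })
  })
}
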