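#' Default fire regime parameters for a synthetic environment
#'
#' Derives per-cell fire regime parameters from the rainfall surface. The
#' defaults encode the qualitative continental pattern: fire activity and --
#' more importantly for the pyrodiversity index -- the *dispersion* of fire
#' attributes (size spread, season spread, intensity spread) decline as mean
#' annual precipitation rises above the 650 mm wet-savanna threshold, while
#' fire timing concentrates in the local dry season (about half a year after
#' the peak rain month). This makes downstream pyrodiversity highest in dry
#' savannas and declining with rainfall above 650 mm.
#'
#' @param env a [gen_environment()] stack.
#' @param fires_per_year_dry expected fires per cell-year in dry savanna.
#' @param detection_rate probability that a burning pixel-observation yields
#'   an active-fire detection (uniform; no sensor artefacts are emulated).
#' @param spread_days_max maximum within-fire spread window in days.
#' @return object of class `pd_regime`: per-cell rates and lognormal
#'   size/intensity parameters, circular season parameters, plus the scalar
#'   detection rate and spread window.
#' @export
fire_regime <- function(env, fires_per_year_dry = 6, detection_rate = 0.7,
                        spread_days_max = 8) {
  stopifnot(inherits(env, "pd_env"))
  cells <- env$cells
  w <- pmin(pmax((cells$map_mm - 650) / 750, 0), 1)  # 0 dry -> 1 wettest
  peak_fire_doy <- ((cells$peak_month - 1) * 30.4 + 14 + 182) %% 365
  regime <- tibble(
    cell_id = cells$cell_id,
    rate = fires_per_year_dry * exp(-1.0 * w),
    size_meanlog = log(60) - 0.5 * w,   # km^2
    size_sdlog = 0.9 - 0.5 * w,
    season_peak_doy = peak_fire_doy,
    season_sd_days = 70 - 40 * w,
    frp_meanlog = log(30) + 0.3 * (1 - w),  # MW
    frp_sdlog = 0.8 - 0.4 * w
  )
  structure(list(cells = regime, detection_rate = detection_rate,
                 spread_days_max = spread_days_max),
            class = "pd_regime")
}

#' Generate a multi-year synthetic fire history
#'
#' Simulates individual fires and renders them into per-year burn-date
#' rasters (integer days since 2000-01-01, `NA` = unburned) plus a table of
#' active-fire detections with radiative power, emulating the paired
#' burned-area / active-fire satellite products the delineation stage
#' ingests. Fire counts per cell-year are Poisson; footprints grow by
#' stochastic region-growing from an ignition pixel, with per-pixel burn
#' dates advancing linearly over a spread window of at most
#' `regime$spread_days_max` days (so multi-day fires exist and exercise the
#' date-gap rule); sizes and radiative powers are lognormal; ignition timing
#' is wrapped-normal around the cell's dry-season peak. Pixels already burned
#' in the same year are not re-burned.
#'
#' @param env a [gen_environment()] stack.
#' @param regime a [fire_regime()]; default derives one from `env`.
#' @param years number of years simulated (at least 2: fire return intervals
#'   need a prior burn on record).
#' @param seed integer seed; output is deterministic in `(env, regime,
#'   years, seed)`.
#' @return a list with `burn` (class `pd_burn`: `grid` + `layers`, one
#'   integer matrix per year), `detections` (tibble: `lon`, `lat`, `date`,
#'   `frp_mw`) and `fires_true` (tibble of simulated fires with list-columns
#'   of pixel rows/cols/dates -- the generator's ground truth).
#' @export
gen_fire_history <- function(env, regime = NULL, years = 12, seed = 1) {
  stopifnot(inherits(env, "pd_env"))
  if (years < 2) abort("years must be >= 2: fire return intervals need a prior burn")
  regime <- regime %||% fire_regime(env)
  grid <- env$grid
  ppc <- grid$pixels_per_cell
  px_area <- grid$pixel_area_km2

  with_seed(derive_seed(seed, "fire_history"), {
    layers <- lapply(seq_len(years), function(y)
      matrix(NA_integer_, grid$px_rows, grid$px_cols))
    rc <- regime$cells
    cells <- env$cells

    det_lon <- numeric(0); det_lat <- numeric(0)
    det_date <- integer(0); det_frp <- numeric(0)
    tr <- list()
    fid <- 0L

    year_day0 <- pd_date2day(as.Date(sprintf("%d-01-01", 2000 + seq_len(years) - 1)))

    for (y in seq_len(years)) {
      layer <- layers[[y]]
      n_cell_fires <- rpois(nrow(rc), rc$rate)
      for (ci in which(n_cell_fires > 0)) {
        crow <- cells$cell_row[ci]; ccol <- cells$cell_col[ci]
        for (k in seq_len(n_cell_fires[ci])) {
          doy <- as.integer(round(rnorm(1, 0, rc$season_sd_days[ci]) +
                                    rc$season_peak_doy[ci])) %% 365L
          ign_date <- year_day0[y] + doy
          n_px <- max(1L, min(200L, as.integer(round(
            exp(rnorm(1, rc$size_meanlog[ci], rc$size_sdlog[ci])) / px_area))))
          spread <- min(regime$spread_days_max, max(0L, n_px - 1L))

          # ignition pixel uniform within the cell
          pr <- (crow - 1L) * ppc + sample.int(ppc, 1)
          pc <- (ccol - 1L) * ppc + sample.int(ppc, 1)
          if (!is.na(layer[pr, pc])) next  # ignition point already burned
          fid <- fid + 1L
          rows <- integer(n_px); cols <- integer(n_px); dts <- integer(n_px)
          rows[1] <- pr; cols[1] <- pc; dts[1] <- ign_date
          layer[pr, pc] <- ign_date
          got <- 1L
          # frontier: 4-neighbours of the patch, unburned, in-grid
          fr_r <- integer(0); fr_c <- integer(0)
          add_frontier <- function(r, c) {
            nr <- c(r - 1L, r + 1L, r, r); ncl <- c(c, c, c - 1L, c + 1L)
            ok <- nr >= 1 & nr <= grid$px_rows & ncl >= 1 & ncl <= grid$px_cols
            nr <- nr[ok]; ncl <- ncl[ok]
            ok <- is.na(layer[cbind(nr, ncl)])
            list(r = nr[ok], c = ncl[ok])
          }
          f <- add_frontier(pr, pc)
          fr_r <- f$r; fr_c <- f$c
          while (got < n_px && length(fr_r) > 0) {
            j <- if (length(fr_r) == 1) 1L else sample.int(length(fr_r), 1)
            r <- fr_r[j]; c <- fr_c[j]
            fr_r <- fr_r[-j]; fr_c <- fr_c[-j]
            if (!is.na(layer[r, c])) next
            got <- got + 1L
            d <- ign_date + as.integer(floor((got - 1L) / max(1L, n_px - 1L) * spread))
            rows[got] <- r; cols[got] <- c; dts[got] <- d
            layer[r, c] <- d
            f <- add_frontier(r, c)
            fr_r <- c(fr_r, f$r); fr_c <- c(fr_c, f$c)
          }
          rows <- rows[seq_len(got)]; cols <- cols[seq_len(got)]
          dts <- dts[seq_len(got)]

          # active-fire detections: per pixel-observation, thinned
          frp_fire <- rnorm(1, rc$frp_meanlog[ci], rc$frp_sdlog[ci])
          hit <- runif(got) < regime$detection_rate
          if (any(hit)) {
            jit_x <- runif(sum(hit), -0.4, 0.4) * grid$pixel_deg
            jit_y <- runif(sum(hit), -0.4, 0.4) * grid$pixel_deg
            det_lon <- c(det_lon, pixel_lon(grid, cols[hit]) + jit_x)
            det_lat <- c(det_lat, pixel_lat(grid, rows[hit]) + jit_y)
            det_date <- c(det_date, dts[hit])
            det_frp <- c(det_frp, exp(rnorm(sum(hit), frp_fire, 0.3)))
          }

          tr[[fid]] <- list(fire_id = fid, cell_id = cells$cell_id[ci],
                            year = y, ignition_date = ign_date,
                            n_pixels = got, frp_meanlog = frp_fire,
                            px_row = rows, px_col = cols, px_date = dts)
        }
      }
      layers[[y]] <- layer
    }

    fires_true <- if (length(tr) == 0) {
      tibble(fire_id = integer(0), cell_id = integer(0), year = integer(0),
             ignition_date = integer(0), n_pixels = integer(0),
             frp_meanlog = numeric(0), px_row = list(), px_col = list(),
             px_date = list())
    } else {
      tibble(
        fire_id = vapply(tr, `[[`, 0L, "fire_id"),
        cell_id = vapply(tr, `[[`, 0L, "cell_id"),
        year = vapply(tr, `[[`, 0L, "year"),
        ignition_date = vapply(tr, `[[`, 0L, "ignition_date"),
        n_pixels = vapply(tr, `[[`, 0L, "n_pixels"),
        frp_meanlog = vapply(tr, `[[`, 0, "frp_meanlog"),
        px_row = lapply(tr, `[[`, "px_row"),
        px_col = lapply(tr, `[[`, "px_col"),
        px_date = lapply(tr, `[[`, "px_date")
      )
    }
    list(
      burn = structure(list(grid = grid, layers = layers), class = "pd_burn"),
      detections = tibble(lon = det_lon, lat = det_lat, date = det_date,
                          frp_mw = det_frp),
      fires_true = fires_true
    )
  })
}

#' @export
print.pd_burn <- function(x, ...) {
  nb <- sum(vapply(x$layers, function(l) sum(!is.na(l)), 0))
  cat(sprintf("<pd_burn> %d year layers, %d burned pixel-observations\n",
              length(x$layers), nb))
  invisible(x)
}
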