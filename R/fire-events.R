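#' Delineate individual fires from burn-date rasters
#'
#' Identifies individual fires by spatiotemporal flood fill over burned
#' pixel-observations. An observation is one (pixel, burn date) pair; a pixel
#' burning in several years contributes one observation per burn. Two
#' observations belong to the same fire exactly when they are connected by a
#' chain of observations whose pixels are identical or adjacent (4- or
#' 8-connectivity) and whose dates differ pairwise along the chain by at most
#' `date_gap_days`. Long-running fires are therefore allowed: grouping is by
#' the chain rule, not by total date span.
#'
#' @param burn a `pd_burn` object (per-year integer burn-date matrices, days
#'   since 2000-01-01, `NA` = unburned).
#' @param connectivity 4 or 8 (default 8, with an 8-day gap: the compositing
#'   period of the burned-area product).
#' @param date_gap_days maximum date difference (days) across one chain link.
#' @return a tibble with one row per fire: `fire_id` (ordered by ignition
#'   date, then centroid), `n_pixels`, `area_km2`, `logarea`,
#'   `ignition_date`, `last_date`, `lon_c`, `lat_c`, `cell_id` (cell holding
#'   the footprint centroid) and list-columns `px_row`, `px_col`, `px_date`.
#'   Attributes `fireday`, `logfri`, `logfrp` are filled by later stages.
#' @export
delineate_fires <- function(burn, connectivity = 8, date_gap_days = 8) {
  stopifnot(inherits(burn, "pd_burn"))
  if (!connectivity %in% c(4, 8)) abort("connectivity must be 4 or 8")
  if (date_gap_days < 0) abort("date_gap_days must be >= 0")
  grid <- burn$grid

  obs <- burn_observations(burn)
  if (nrow(obs) == 0) return(empty_fire_tibble())

  lab <- floodfill_cpp(obs$row, obs$col, obs$date,
                       grid$px_rows, grid$px_cols,
                       as.integer(connectivity), as.integer(date_gap_days))

  fires <- obs %>%
    mutate(lab = lab) %>%
    group_by(lab) %>%
    summarise(
      n_pixels = dplyr::n(),
      ignition_date = min(.data$date),
      last_date = max(.data$date),
      lon_c = mean(pixel_lon(.env$grid, .data$col)),
      lat_c = mean(pixel_lat(.env$grid, .data$row)),
      px_row = list(.data$row), px_col = list(.data$col),
      px_date = list(.data$date),
      .groups = "drop"
    ) %>%
    arrange(.data$ignition_date, .data$lat_c, .data$lon_c) %>%
    mutate(
      fire_id = row_number(),
      area_km2 = .data$n_pixels * .env$grid$pixel_area_km2,
      logarea = log(.data$area_km2),
      cell_id = cell_of_lonlat(.env$grid, .data$lon_c, .data$lat_c)
    ) %>%
    select("fire_id", "cell_id", "n_pixels", "area_km2", "logarea",
           "ignition_date", "last_date", "lon_c", "lat_c",
           "px_row", "px_col", "px_date")
  fires
}

# all burned pixel-observations of a burn history as a tibble
burn_observations <- function(burn) {
  out <- lapply(burn$layers, function(l) {
    idx <- which(!is.na(l), arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    tibble(row = as.integer(idx[, 1]), col = as.integer(idx[, 2]),
           date = as.integer(l[idx]))
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    tibble(row = integer(0), col = integer(0), date = integer(0))
  } else out
}

empty_fire_tibble <- function() {
  tibble(fire_id = integer(0), cell_id = integer(0), n_pixels = integer(0),
         area_km2 = numeric(0), logarea = numeric(0),
         ignition_date = integer(0), last_date = integer(0),
         lon_c = numeric(0), lat_c = numeric(0),
         px_row = list(), px_col = list(), px_date = list())
}

#' Fire season timing relative to the local rainfall peak
#'
#' Signed number of days between a fire's ignition date (its earliest burn
#' date) and the nearest 15th of the cell's wettest month, computed on the
#' real calendar. The minimal circular difference is returned, in
#' `[-182, 183]`; positive means the fire started after the rainfall peak,
#' and an exact half-year tie resolves to +183.
#'
#' @param ignition_date integer days since 2000-01-01 (vectorised).
#' @param peak_month wettest month of the fire's cell, 1-12 (vectorised).
#' @return integer vector of signed day offsets.
#' @export
compute_fireday <- function(ignition_date, peak_month) {
  stopifnot(all(peak_month %in% 1:12))
  n <- max(length(ignition_date), length(peak_month))
  ignition_date <- rep_len(as.integer(ignition_date), n)
  peak_month <- rep_len(as.integer(peak_month), n)
  ig <- pd_day2date(ignition_date)
  yr <- as.integer(format(ig, "%Y"))
  out <- integer(n)
  for (i in seq_len(n)) {
    cand <- pd_date2day(as.Date(sprintf("%d-%02d-15", yr[i] + (-1:1), peak_month[i])))
    diffs <- ignition_date[i] - cand
    best <- diffs[order(abs(diffs), -diffs)][1]  # tie -> positive side
    out[i] <- best
  }
  out
}

#' Fire return interval of a delineated fire
#'
#' For every pixel of the fire with at least one earlier burn anywhere in the
#' record, the return interval is the number of days between the pixel's burn
#' date in this fire and its most recent earlier burn. `logFRI` is the
#' natural log of the mean of those per-pixel intervals; it is undefined
#' (`NA`, a value rather than an error -- callers decide exclusion) when no
#' pixel of the fire burned before.
#'
#' @param fire one row of [delineate_fires()] output (a list or single-row
#'   tibble with `px_row`, `px_col`, `px_date`).
#' @param burn the `pd_burn` history the fire was delineated from.
#' @return `logFRI` (log days) or `NA_real_`.
#' @export
compute_fri <- function(fire, burn) {
  rows <- fire$px_row[[1]]; cols <- fire$px_col[[1]]; dates <- fire$px_date[[1]]
  prev <- pixel_previous_burn(burn, rows, cols, dates)
  since <- dates - prev
  since <- since[!is.na(prev)]
  if (length(since) == 0) return(NA_real_)
  log(mean(since))
}

# most recent burn date strictly earlier than `dates` for each pixel; NA if none
pixel_previous_burn <- function(burn, rows, cols, dates) {
  n <- length(rows)
  prev <- rep(NA_integer_, n)
  idx <- cbind(rows, cols)
  for (layer in burn$layers) {
    d <- layer[idx]
    upd <- !is.na(d) & d < dates & (is.na(prev) | d > prev)
    prev[upd] <- d[upd]
  }
  prev
}

#' Join active-fire detections to delineated fires
#'
#' A detection matches a fire when it falls inside the fire's pixel footprint
#' and its date lies in `[ignition - pad, last burn + pad]`. A detection
#' matching several fires (possible once padded) is assigned to the fire with
#' the nearest burn-date window, ties to the earlier `fire_id`. `logFRP` is
#' the log mean radiative power (MW) of a fire's matched detections. Fires
#' with no detection are flagged `frp_excluded` -- mirroring the source
#' filtering in which only fires holding both products are analysed --
#' and unmatched detections are dropped.
#'
#' @param fires output of [delineate_fires()].
#' @param detections tibble with `lon`, `lat`, `date`, `frp_mw`.
#' @param grid the [pd_grid()] of the burn rasters.
#' @param temporal_pad_days symmetric date padding (default 2).
#' @return `fires` with `logfrp` and `frp_excluded` columns.
#' @export
attach_frp <- function(fires, detections, grid, temporal_pad_days = 2) {
  if (temporal_pad_days < 0) abort("temporal_pad_days must be >= 0")
  fires$logfrp <- NA_real_
  fires$frp_excluded <- TRUE
  if (nrow(fires) == 0) return(fires)
  if (nrow(detections) == 0) return(fires)

  px <- pixel_of_lonlat(grid, detections$lon, detections$lat)
  # fire footprint lookup: pixel key -> fire ids covering it (with dates)
  foot <- fires %>%
    select("fire_id", "ignition_date", "last_date", "px_row", "px_col") %>%
    tidyr::unnest(c("px_row", "px_col"))
  foot$key <- foot$px_row + (foot$px_col - 1L) * grid$px_rows
  det <- tibble(det_id = seq_len(nrow(detections)),
                key = px$prow + (px$pcol - 1L) * grid$px_rows,
                date = detections$date, frp_mw = detections$frp_mw)

  cand <- dplyr::inner_join(det, foot, by = "key", relationship = "many-to-many") %>%
    filter(.data$date >= .data$ignition_date - .env$temporal_pad_days,
           .data$date <= .data$last_date + .env$temporal_pad_days) %>%
    mutate(date_dist = pmax(0, .data$ignition_date - .data$date,
                            .data$date - .data$last_date)) %>%
    arrange(.data$det_id, .data$date_dist, .data$fire_id) %>%
    distinct(.data$det_id, .keep_all = TRUE)

  if (nrow(cand) > 0) {
    agg <- cand %>%
      group_by(.data$fire_id) %>%
      summarise(logfrp = log(mean(.data$frp_mw)), .groups = "drop")
    m <- match(fires$fire_id, agg$fire_id)
    fires$logfrp <- agg$logfrp[m]
    fires$frp_excluded <- is.na(fires$logfrp)
  }
  fires
}

#' Assemble the analysis fire table
#'
#' Computes the remaining per-fire attributes (`fireday` against the local
#' rainfall peak, `logfri` from the burn history) and keeps only fires with
#' all four attributes defined: fires lacking a return interval (no earlier
#' burn) or a radiative-power match are excluded, and the exclusion counts
#' are recorded in the `exclusions` attribute.
#'
#' @param fires output of [attach_frp()].
#' @param burn the `pd_burn` history.
#' @param cells cell table with `cell_id` and `peak_month` (from
#'   [gen_environment()] or [summarise_climate()]).
#' @return tibble with one row per retained fire: `fire_id`, `cell_id`,
#'   centroid, `n_pixels`, `area_km2` and the four attributes `logarea`,
#'   `fireday`, `logfri`, `logfrp`; attribute `exclusions` is a named count
#'   vector.
#' @export
assemble_fire_table <- function(fires, burn, cells) {
  if (nrow(fires) == 0) {
    out <- tibble(fire_id = integer(0), cell_id = integer(0),
                  lon_c = numeric(0), lat_c = numeric(0),
                  n_pixels = integer(0), area_km2 = numeric(0),
                  logarea = numeric(0), fireday = integer(0),
                  logfri = numeric(0), logfrp = numeric(0),
                  ignition_date = integer(0))
    attr(out, "exclusions") <- c(no_fri = 0L, no_frp = 0L, off_grid = 0L)
    return(out)
  }
  pk <- cells$peak_month[match(fires$cell_id, cells$cell_id)]
  fires$fireday <- NA_integer_
  ok_cell <- !is.na(pk)
  fires$fireday[ok_cell] <- compute_fireday(fires$ignition_date[ok_cell], pk[ok_cell])
  fires$logfri <- vapply(seq_len(nrow(fires)), function(i)
    compute_fri(fires[i, ], burn), numeric(1))

  excl <- c(no_fri = sum(is.na(fires$logfri)),
            no_frp = sum(fires$frp_excluded),
            off_grid = sum(!ok_cell))
  keep <- !is.na(fires$logfri) & !fires$frp_excluded & ok_cell
  out <- fires[keep, c("fire_id", "cell_id", "lon_c", "lat_c", "n_pixels",
                       "area_km2", "logarea", "fireday", "logfri", "logfrp",
                       "ignition_date")]
  attr(out, "exclusions") <- excl
  out
}
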