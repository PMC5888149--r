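#' SD-normalise the four fire attributes
#'
#' Each fire is a point in the 4-dimensional attribute space
#' (`logarea`, `fireday`, `logfri`, `logfrp`). Before hull volumes are
#' comparable the axes must share a scale, so every column is divided by its
#' standard deviation computed over *all* fires in the table (global
#' normalisation: cell volumes then share units across the map). The SD
#' vector is returned for reproducibility.
#'
#' @param fire_table output of [assemble_fire_table()] (or any data frame
#'   holding the four attribute columns with no missing values).
#' @param attributes column names of the four attributes.
#' @return list with `matrix` (n x 4, normalised), `sds` (named), and
#'   `provenance = "global"`.
#' @export
normalise_attributes <- function(fire_table,
                                 attributes = c("logarea", "fireday",
                                                "logfri", "logfrp")) {
  if (nrow(fire_table) < 2) abort("need at least 2 fires to normalise")
  m <- as.matrix(fire_table[, attributes])
  storage.mode(m) <- "double"
  if (any(is.na(m))) abort("attribute matrix has missing values")
  sds <- apply(m, 2, stats::sd)
  zero <- sds <= 0 | !is.finite(sds)
  if (any(zero)) {
    abort(paste0("zero-variance attribute(s): ",
                 paste(attributes[zero], collapse = ", ")))
  }
  list(matrix = sweep(m, 2, sds, "/"), sds = setNames(sds, attributes),
       provenance = "global")
}

#' Per-cell pyrodiversity and fire-attribute summaries
#'
#' Groups fires by their assigned grid cell and computes, per cell: the
#' pyrodiversity index (bootstrap-corrected 4D convex-hull volume of the
#' globally SD-normalised attributes, see [bootstrap_corrected_volume()]),
#' the mean of each attribute on its stored scale (logs where applicable),
#' and coefficients of variation. CVs are taken on positive re-expressions --
#' area in km^2, return interval in days, radiative power in MW -- because a
#' CV of a signed or logged quantity is ill-defined; season variability is
#' the circular SD of ignition day-of-year divided by 365. Cells with fewer
#' than `n_min` fires get missing pyrodiversity and CVs (4D hulls on few
#' points are degeneracy-dominated) but keep their attribute means.
#'
#' Bootstrap resampling is seeded per cell from `(seed, cell_id)` and fires
#' are processed in `fire_id` order, so results are invariant to row
#' permutation of the fire table.
#'
#' @param fire_table output of [assemble_fire_table()].
#' @param n_min minimum fires per cell for pyrodiversity and CVs.
#' @param B bootstrap resamples per cell.
#' @param seed integer seed.
#' @param method bootstrap mode, see [bootstrap_corrected_volume()].
#' @return tibble with `cell_id`, `n_fires`, `pyrodiversity`, the four
#'   `mean_*` columns and the four `cv_*` columns.
#' @export
cell_summaries <- function(fire_table, n_min = 10, B = 200, seed = 1,
                           method = "bias") {
  norm <- normalise_attributes(fire_table)
  ft <- fire_table %>%
    mutate(.norm_row = row_number()) %>%
    arrange(.data$cell_id, .data$fire_id)
  doy <- as.integer(format(pd_day2date(ft$ignition_date), "%j"))
  ft$ign_doy <- doy

  groups <- split(seq_len(nrow(ft)), ft$cell_id)
  out <- lapply(names(groups), function(cid) {
    i <- groups[[cid]]
    g <- ft[i, ]
    nf <- nrow(g)
    res <- tibble(
      cell_id = as.integer(cid), n_fires = nf,
      pyrodiversity = NA_real_,
      mean_logarea = mean(g$logarea),
      mean_fireday = mean(g$fireday),
      mean_logfri = mean(g$logfri),
      mean_logfrp = mean(g$logfrp),
      cv_area = NA_real_, cv_fireday = NA_real_,
      cv_fri = NA_real_, cv_frp = NA_real_
    )
    if (nf >= n_min) {
      pts <- norm$matrix[g$.norm_row, , drop = FALSE]
      res$pyrodiversity <- bootstrap_corrected_volume(
        pts, B = B, seed = derive_seed(seed, paste0("cell", cid)),
        method = method)
      res$cv_area <- stats::sd(g$area_km2) / mean(g$area_km2)
      fri_days <- exp(g$logfri)
      res$cv_fri <- stats::sd(fri_days) / mean(fri_days)
      frp_mw <- exp(g$logfrp)
      res$cv_frp <- stats::sd(frp_mw) / mean(frp_mw)
      res$cv_fireday <- circular_sd_days(g$ign_doy) / 365
    }
    res
  })
  out <- bind_rows(out)
  attr(out, "attribute_sds") <- norm$sds
  out
}
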