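#' Map a per-cell quantity
#'
#' Tile map of any cell-level column (pyrodiversity, richness, MAP, ...).
#'
#' @param cells a cell table with `lon_c`, `lat_c` and the mapped column.
#' @param fill column to map (tidy-eval).
#' @return a ggplot object.
#' @export
plot_cell_map <- function(cells, fill) {
  ggplot2::ggplot(cells, ggplot2::aes(.data$lon_c, .data$lat_c,
                                      fill = {{ fill }})) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude", y = "latitude")
}

#' Plot a posterior richness curve over pyrodiversity
#'
#' @param curve output of [predicted_richness_curve()] (optionally
#'   row-bound over strata with a `stratum` column).
#' @return a ggplot object.
#' @export
plot_richness_curve <- function(curve) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(.data$pyrodiversity, .data$median))
  if ("stratum" %in% names(curve)) {
    p <- p + ggplot2::aes(colour = .data$stratum, fill = .data$stratum)
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pyrodiversity", y = "predicted richness")
}

#' Forest plot of per-stratum fire-covariate effects
#'
#' @param object a [fit_car_model()] object (or an [effects_table()] tibble
#'   via `plot_effects()`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pd_car_fit <- function(object, ...) {
  plot_effects(effects_table(object))
}

#' @rdname autoplot.pd_car_fit
#' @param effects an [effects_table()] tibble.
#' @export
plot_effects <- function(effects) {
  ggplot2::ggplot(effects,
                  ggplot2::aes(.data$median, .data$covariate,
                               colour = .data$stratum,
                               alpha = .data$supported)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "effect (per SD, log richness scale)", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
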