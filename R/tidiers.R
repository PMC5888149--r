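#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy posterior summaries of a spatial richness fit
#'
#' One row per fixed-effect coefficient: posterior median, 95% credible
#' interval, R-hat, and the interval-excludes-zero support flag.
#'
#' @param x a [fit_car_model()] object.
#' @param ... unused.
#' @return a tibble with `term`, `estimate`, `conf.low`, `conf.high`,
#'   `rhat`, `supported`.
#' @export
tidy.pd_car_fit <- function(x, ...) {
  q <- apply(x$beta, 2, quantile, c(0.025, 0.5, 0.975))
  tibble(
    term = colnames(x$beta),
    estimate = q[2, ],
    conf.low = q[1, ],
    conf.high = q[3, ],
    rhat = unname(x$rhat[colnames(x$beta)]),
    supported = q[1, ] > 0 | q[3, ] < 0
  )
}

#' One-row model summary of a spatial richness fit
#'
#' @param x a [fit_car_model()] object.
#' @param ... unused.
#' @return a tibble with `waic`, `lppd`, `p_waic`, `n`, `n_draws`, `chains`,
#'   `max_rhat`, `converged`.
#' @export
glance.pd_car_fit <- function(x, ...) {
  tibble(
    waic = x$waic$waic, lppd = x$waic$lppd, p_waic = x$waic$p_waic,
    n = ncol(x$ll), n_draws = nrow(x$beta),
    chains = length(unique(x$chain_id)),
    max_rhat = max(x$rhat), converged = x$converged
  )
}
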