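#' Build the inside/outside protected-area cell table
#'
#' For every protected area: *inside* cells are those at least
#' `pa_threshold`-covered by that PA; *outside* cells are non-PA cells (below
#' the threshold for every PA) with at least `inclusion_frac` of their area
#' within `buffer_km` of the PA boundary. Buffer membership is measured on a
#' regular subgrid of points per cell, with planar distances in km from the
#' grid metadata. Cells inside another PA never qualify as outside. PAs with
#' no qualifying inside or outside cells are dropped with a warning. A cell
#' may appear once per PA whose buffer reaches it: `(cell, pa)` pairs are
#' unique.
#'
#' @param cells cell table carrying `cell_id`, bounds, and the per-cell fire
#'   metrics to contrast (e.g. from [build_cell_table()]).
#' @param pa_polys protected-area polygon tibble.
#' @param grid the [pd_grid()] (supplies km per degree).
#' @param buffer_km buffer distance around each PA (100 km, the scale of a
#'   typical large PA; 50 km behaves similarly).
#' @param inclusion_frac minimum fraction of a cell inside the buffer.
#' @param pa_threshold coverage fraction defining "inside".
#' @param subgrid points per cell side for the area fractions.
#' @return tibble: `cells` columns plus `pa_id` and `status`
#'   (`"inside"`/`"outside"`).
#' @export
build_buffer_table <- function(cells, pa_polys, grid, buffer_km = 100,
                               inclusion_frac = 0.2, pa_threshold = 0.5,
                               subgrid = 5) {
  stopifnot(buffer_km > 0, inclusion_frac > 0, inclusion_frac <= 1)
  rings <- polys_to_rings(pa_polys)
  if (length(rings) == 0) {
    return(dplyr::slice(mutate(cells, pa_id = NA_character_,
                               status = NA_character_), 0))
  }
  cell_area <- (cells$lon_max - cells$lon_min) * (cells$lat_max - cells$lat_min)

  # per-PA coverage fraction of each cell
  cover <- vapply(rings, function(ring) {
    vapply(seq_len(nrow(cells)), function(i)
      ring_rect_intersection_area(ring, cells$lon_min[i], cells$lon_max[i],
                                  cells$lat_min[i], cells$lat_max[i]) /
        cell_area[i], 0)
  }, numeric(nrow(cells)))
  inside_any <- apply(cover >= pa_threshold, 1, any)

  # subgrid points per cell, in km coordinates
  g <- seq_len(subgrid) / subgrid - 1 / (2 * subgrid)
  off_x <- rep(g, times = subgrid); off_y <- rep(g, each = subgrid)
  out <- list()
  for (k in seq_along(rings)) {
    pa_id <- names(rings)[k]
    ring_km <- rings[[k]] * grid$km_per_deg
    inside_cells <- which(cover[, k] >= pa_threshold)
    px <- rep(cells$lon_min, each = length(off_x)) +
      rep(off_x, times = nrow(cells)) * rep(cells$lon_max - cells$lon_min,
                                            each = length(off_x))
    py <- rep(cells$lat_min, each = length(off_y)) +
      rep(off_y, times = nrow(cells)) * rep(cells$lat_max - cells$lat_min,
                                            each = length(off_y))
    dkm <- dist_to_ring(px * grid$km_per_deg, py * grid$km_per_deg, ring_km)
    frac_buf <- colMeans(matrix(dkm <= buffer_km, nrow = length(off_x)))
    outside_cells <- which(!inside_any & frac_buf >= inclusion_frac)
    if (length(inside_cells) == 0 || length(outside_cells) == 0) {
      warn(sprintf("protected area %s has no qualifying %s cells; dropped",
                   pa_id,
                   if (length(inside_cells) == 0) "inside" else "outside"))
      next
    }
    out[[pa_id]] <- bind_rows(
      mutate(cells[inside_cells, ], pa_id = pa_id, status = "inside"),
      mutate(cells[outside_cells, ], pa_id = pa_id, status = "outside")
    )
  }
  bind_rows(out)
}

#' Gaussian random-intercept model by profile REML
#'
#' Fits `y = beta0 + beta_status * status + b_group + e`, with
#' `b_group ~ N(0, sigma_g^2)` and `e ~ N(0, sigma^2)`, by REML: the variance
#' ratio `lambda = sigma_g^2 / sigma^2` is profiled out with closed-form GLS
#' at each candidate value and optimised numerically; the grouped structure
#' makes every quantity computable per group without forming n x n matrices.
#'
#' @param y numeric response.
#' @param status factor or character ("inside"/"outside") or 0/1 numeric;
#'   the fixed effect is the inside-minus-outside contrast.
#' @param group grouping factor (PA identity).
#' @return list with `beta_status`, `se`, `sigma2_group`, `sigma2_resid`,
#'   `lambda`, `n_obs`, `n_groups`, `reml_criterion`, `singular` flag and
#'   `beta0`.
#' @export
fit_random_intercept <- function(y, status, group) {
  ok <- !is.na(y)
  y <- y[ok]; status <- status[ok]; group <- group[ok]
  if (length(unique(group)) < 2) abort("need at least 2 groups")
  x <- if (is.numeric(status)) as.numeric(status) else
    as.numeric(status == "inside")
  X <- cbind(1, x)
  crit <- function(log_lambda) reml_criterion(y, X, group, exp(log_lambda))
  opt <- optimize(crit, c(-12, 12))
  lambda <- exp(opt$minimum)
  c0 <- reml_criterion(y, X, group, 0)
  if (c0 <= opt$objective + 1e-10) {
    lambda <- 0
  }
  sol <- reml_solve(y, X, group, lambda)
  list(
    beta0 = unname(sol$beta[1]), beta_status = unname(sol$beta[2]),
    se = unname(sol$se[2]),
    sigma2_group = lambda * sol$sigma2, sigma2_resid = sol$sigma2,
    lambda = lambda, n_obs = length(y), n_groups = length(unique(group)),
    reml_criterion = reml_criterion(y, X, group, lambda),
    singular = lambda <= 1e-8
  )
}

#' REML profile criterion for the random-intercept model
#'
#' The quantity [fit_random_intercept()] minimises over the variance ratio
#' `lambda`: `(n - p) log(sigma2_hat) + log|V| + log|X' V^-1 X|` with
#' `V = I + lambda Z Z'` (up to an additive constant). Exposed so that
#' optimisation can be checked against direct grid search.
#'
#' @param y response vector.
#' @param X fixed-effects design matrix.
#' @param group grouping factor.
#' @param lambda variance ratio (>= 0).
#' @return scalar criterion value.
#' @export
reml_criterion <- function(y, X, group, lambda) {
  s <- reml_solve(y, X, group, lambda)
  n <- length(y); p <- ncol(X)
  (n - p) * log(s$sigma2) + s$logdet_v + s$logdet_xvx
}

# groupwise GLS for V = I + lambda * J within each group
reml_solve <- function(y, X, group, lambda) {
  n <- length(y); p <- ncol(X)
  gs <- split(seq_len(n), group)
  A <- matrix(0, p, p); b <- numeric(p)
  yvy <- 0; logdet_v <- 0
  for (i in gs) {
    ng <- length(i)
    Xg <- X[i, , drop = FALSE]; yg <- y[i]
    cg <- lambda / (1 + lambda * ng)
    sx <- colSums(Xg); sy <- sum(yg)
    A <- A + crossprod(Xg) - cg * tcrossprod(sx)
    b <- b + crossprod(Xg, yg) - cg * sx * sy
    yvy <- yvy + sum(yg^2) - cg * sy^2
    logdet_v <- logdet_v + log(1 + lambda * ng)
  }
  beta <- solve(A, b)
  q <- yvy - sum(b * beta)
  sigma2 <- max(q / (n - p), 1e-300)
  Ainv <- solve(A)
  list(beta = drop(beta), se = sqrt(pmax(diag(Ainv), 0) * sigma2),
       sigma2 = sigma2, logdet_v = logdet_v,
       logdet_xvx = determinant(A, logarithm = TRUE)$modulus[1])
}

#' Inside/outside contrast across all fire metrics
#'
#' Fits one random-intercept model per metric (pyrodiversity, the four
#' attribute means and the four CVs by default) on a [build_buffer_table()]
#' and reports the inside-effect estimate with its standard error.
#'
#' @param buffer_table output of [build_buffer_table()].
#' @param metrics columns to contrast.
#' @return tibble: `metric`, `beta`, `se`, `sigma2_pa`, `sigma2_resid`,
#'   `n_obs`, `n_pa`, `singular`.
#' @export
contrast_report <- function(buffer_table,
                            metrics = c("pyrodiversity", "mean_logarea",
                                        "mean_fireday", "mean_logfri",
                                        "mean_logfrp", "cv_area",
                                        "cv_fireday", "cv_fri", "cv_frp")) {
  metrics <- intersect(metrics, names(buffer_table))
  purrr::map_dfr(metrics, function(m) {
    f <- fit_random_intercept(buffer_table[[m]], buffer_table$status,
                              buffer_table$pa_id)
    tibble(metric = m, beta = f$beta_status, se = f$se,
           sigma2_pa = f$sigma2_group, sigma2_resid = f$sigma2_resid,
           n_obs = f$n_obs, n_pa = f$n_groups, singular = f$singular)
  })
}
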