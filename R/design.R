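#' Specify a richness model
#'
#' Describes one model of the two classes fitted per richness group: fire
#' covariates are either pyrodiversity plus the four attribute *means*, or
#' pyrodiversity plus the four attribute *CVs* -- never mixed, because means
#' and CVs of the same attributes are strongly correlated. Every fire
#' covariate enters stratified by the wet/dry rainfall split (a `c_wet` and a
#' `c_dry` column, giving per-stratum effects directly); the quadratic
#' variant appends squared standardised fire covariates, also stratified.
#' Richness is modelled as Poisson with log link, iid lognormal
#' overdispersion and an intrinsic CAR spatial effect; a Gaussian mode for
#' continuous responses sits behind `likelihood`.
#'
#' @param model_class `"means"` or `"cv"`.
#' @param response name of the response column (non-negative integer counts
#'   for the Poisson likelihood).
#' @param quadratic add squared fire-covariate terms.
#' @param fire_covariates optional character vector overriding the class's
#'   covariate set (may be empty; `"pyrodiversity"` alone gives the
#'   single-covariate model used in simulation experiments).
#' @param likelihood `"poisson"` (default) or `"gaussian"`.
#' @param chains,iter,burnin,thin MCMC settings (2 chains of 4000 iterations,
#'   half burn-in, by default).
#' @param prior_beta_sd SD of the vague Normal prior on fixed effects
#'   (standardised scale).
#' @param prior_tau_shape,prior_tau_rate Gamma prior on both random-effect
#'   precisions (log-gamma on the log precision), shape 0.1 and rate 0.5.
#' @param min_stratum_cells smallest wet or dry cell count for which the
#'   stratified interaction is estimable.
#' @param seed integer seed for the sampler.
#' @return object of class `pd_model_spec`.
#' @export
model_spec <- function(model_class = c("means", "cv"),
                       response = "richness_sim", quadratic = FALSE,
                       fire_covariates = NULL,
                       likelihood = c("poisson", "gaussian"),
                       chains = 2, iter = 4000, burnin = iter / 2, thin = 1,
                       prior_beta_sd = 10, prior_tau_shape = 0.1,
                       prior_tau_rate = 0.5, min_stratum_cells = 10,
                       seed = 1) {
  model_class <- match.arg(model_class)
  likelihood <- match.arg(likelihood)
  if (is.null(fire_covariates)) {
    fire_covariates <- if (model_class == "means") {
      c("pyrodiversity", "mean_logarea", "mean_fireday", "mean_logfri",
        "mean_logfrp")
    } else {
      c("pyrodiversity", "cv_area", "cv_fireday", "cv_fri", "cv_frp")
    }
  }
  structure(list(
    model_class = model_class, response = response, quadratic = quadratic,
    fire_covariates = fire_covariates, likelihood = likelihood,
    chains = chains, iter = iter, burnin = burnin, thin = thin,
    prior_beta_sd = prior_beta_sd, prior_tau_shape = prior_tau_shape,
    prior_tau_rate = prior_tau_rate, min_stratum_cells = min_stratum_cells,
    seed = seed
  ), class = "pd_model_spec")
}

#' Build the design matrix for a richness model
#'
#' Restricts to analysis cells with complete covariates (listwise deletion;
#' the dropped count is recorded), z-scores all continuous covariates
#' (constants stored for prediction), and assembles: intercept, a cubic
#' B-spline basis of standardised NPP with two interior knots at its 33rd and
#' 67th percentiles, standardised topographic heterogeneity, the wet
#' indicator, and a `_wet`/`_dry` column pair per fire covariate (plus
#' squared pairs in the quadratic variant).
#'
#' @param cells output of [build_cell_table()] (or any tibble with the
#'   needed columns and an `in_analysis` flag).
#' @param spec a [model_spec()].
#' @return object of class `pd_design`: list with `X`, `y`, `cells` (kept
#'   rows), `scaling` (tibble of centre/scale per covariate), `n_dropped`
#'   and `spec`.
#' @export
build_design <- function(cells, spec) {
  stopifnot(inherits(spec, "pd_model_spec"))
  need <- c(spec$response, "npp", "topo_het", "is_wet", spec$fire_covariates)
  miss <- setdiff(need, names(cells))
  if (length(miss) > 0) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  keep <- cells$in_analysis & complete.cases(cells[, need])
  n_dropped <- sum(cells$in_analysis) - sum(keep)
  d <- cells[keep, ]
  wet <- as.numeric(d$is_wet)
  if (sum(wet) < spec$min_stratum_cells || sum(1 - wet) < spec$min_stratum_cells) {
    abort(sprintf("a rainfall stratum has < %d cells: stratified effects inestimable",
                  spec$min_stratum_cells))
  }
  y <- d[[spec$response]]
  if (spec$likelihood == "poisson" &&
      (any(y < 0) || any(y != round(y)))) {
    abort("Poisson likelihood needs non-negative integer counts")
  }

  scaling <- list()
  zs <- function(x, name) {
    mu <- mean(x); s <- stats::sd(x)
    if (s == 0) abort(paste0("zero-variance covariate: ", name))
    scaling[[name]] <<- tibble(covariate = name, center = mu, scale = s)
    (x - mu) / s
  }
  npp_z <- zs(d$npp, "npp")
  topo_z <- zs(d$topo_het, "topo_het")
  knots <- quantile(npp_z, c(1 / 3, 2 / 3))
  spl <- splines::bs(npp_z, degree = 3, knots = knots,
                     Boundary.knots = range(npp_z))
  colnames(spl) <- paste0("npp_bs", seq_len(ncol(spl)))

  X <- cbind(`(Intercept)` = 1, spl, topo_het = topo_z, wet = wet)
  for (cv in spec$fire_covariates) {
    cz <- zs(d[[cv]], cv)
    X <- cbind(X, cz * wet, cz * (1 - wet))
    colnames(X)[ncol(X) - 1:0] <- paste0(cv, c("_wet", "_dry"))
  }
  if (spec$quadratic) {
    for (cv in spec$fire_covariates) {
      cz <- (d[[cv]] - scaling[[cv]]$center) / scaling[[cv]]$scale
      X <- cbind(X, cz^2 * wet, cz^2 * (1 - wet))
      colnames(X)[ncol(X) - 1:0] <- paste0(cv, c("_sq_wet", "_sq_dry"))
    }
  }
  structure(list(
    X = X, y = y, cells = d, scaling = bind_rows(scaling),
    n_dropped = n_dropped, spline_knots = knots, spec = spec
  ), class = "pd_design")
}

#' Queen adjacency over analysis cells
#'
#' Symmetric 8-neighbour (queen) adjacency between the retained cells of a
#' design, with neighbour counts, the edge list, island cells (no
#' neighbours) and the number of connected components of the non-island
#' subgraph -- the quantities the intrinsic CAR update needs.
#'
#' @param cells tibble with `cell_row` and `cell_col` (e.g. `design$cells`).
#' @return object of class `pd_adjacency`.
#' @export
build_adjacency <- function(cells) {
  n <- nrow(cells)
  key <- cells$cell_row * 1e6 + cells$cell_col
  idx <- seq_len(n)
  edges_i <- integer(0); edges_j <- integer(0)
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  lookup <- setNames(idx, key)
  for (k in seq_len(nrow(off))) {
    nb_key <- (cells$cell_row + off$dr[k]) * 1e6 + (cells$cell_col + off$dc[k])
    j <- lookup[as.character(nb_key)]
    ok <- !is.na(j)
    edges_i <- c(edges_i, idx[ok]); edges_j <- c(edges_j, j[ok])
  }
  # each undirected edge appears twice; keep i < j for the edge list
  W <- Matrix::sparseMatrix(i = edges_i, j = edges_j, x = 1, dims = c(n, n))
  el <- cbind(edges_i, edges_j)[edges_i < edges_j, , drop = FALSE]
  n_nb <- Matrix::rowSums(W)
  islands <- which(n_nb == 0)
  # connected components of the non-island subgraph (BFS)
  comp <- rep(0L, n)
  ncomp <- 0L
  for (s in idx) {
    if (comp[s] != 0L || n_nb[s] == 0) next
    ncomp <- ncomp + 1L
    queue <- s; comp[s] <- ncomp
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      nbs <- c(el[el[, 1] == v, 2], el[el[, 2] == v, 1])
      new <- nbs[comp[nbs] == 0L]
      comp[new] <- ncomp
      queue <- c(queue, new)
    }
  }
  structure(list(W = W, n_nb = as.numeric(n_nb), edges = el,
                 islands = islands, n = n, n_components = ncomp,
                 icar_rank = sum(n_nb > 0) - ncomp),
            class = "pd_adjacency")
}
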