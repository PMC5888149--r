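#' Fit a Bayesian spatial richness model by MCMC
#'
#' Fits the hierarchical model: counts `y_i ~ Poisson(exp(eta_i))` with
#' `eta_i = x_i' beta + phi_i + eps_i`, where `phi` is an intrinsic CAR
#' (Besag) spatial effect on the queen adjacency with a sum-to-zero
#' constraint, `eps` is iid Gaussian overdispersion, fixed effects have vague
#' Normal(0, `prior_beta_sd`^2) priors and both random-effect precisions have
#' Gamma(0.1, 0.5) priors (log-gamma on the log precision). Inference is
#' Metropolis-within-Gibbs: the latent `eta` gets vectorised adaptive
#' random-walk Metropolis updates (conditionally independent across cells),
#' `beta` and `phi` conjugate Gaussian updates (`phi` by chromatic Gibbs over
#' the 4-colouring of the queen lattice), and the precisions conjugate Gamma
#' updates. Island cells keep a zero spatial effect. The Gaussian mode drops
#' the latent layer and runs fully conjugate Gibbs on `y = X beta + phi +
#' eps`.
#'
#' Convergence is summarised by split-R-hat over chains for all fixed effects
#' and precisions; a fit with any R-hat above 1.05 is returned flagged, never
#' silently.
#'
#' @param design a [build_design()] object.
#' @param adjacency optional [build_adjacency()]; built from the design's
#'   cells when omitted.
#' @param tau_phi_fixed,tau_eps_fixed optionally fix a precision (used in
#'   conjugate cross-checks).
#' @return object of class `pd_car_fit`: posterior draw matrices (`beta`,
#'   `tau_phi`, `tau_eps`, chain ids), spatial-field posterior mean, a
#'   pointwise log-likelihood matrix for wAIC, R-hat values, the `converged`
#'   flag and the design.
#' @export
fit_car_model <- function(design, adjacency = NULL,
                          tau_phi_fixed = NULL, tau_eps_fixed = NULL) {
  stopifnot(inherits(design, "pd_design"))
  spec <- design$spec
  adjacency <- adjacency %||% build_adjacency(design$cells)
  X <- design$X; y <- design$y
  n <- length(y); p <- ncol(X)
  stopifnot(adjacency$n == n)

  W <- adjacency$W; n_nb <- adjacency$n_nb; el <- adjacency$edges
  non_island <- n_nb > 0
  colour <- (design$cells$cell_row %% 2) * 2 + design$cells$cell_col %% 2
  colour_sets <- split(seq_len(n), colour)
  # pre-subset per colour: non-island members, their rows of W, their degrees
  cs_idx <- lapply(colour_sets, function(cs) cs[n_nb[cs] > 0])
  cs_W <- lapply(cs_idx, function(cs) adjacency$W[cs, , drop = FALSE])
  cs_nnb <- lapply(cs_idx, function(cs) adjacency$n_nb[cs])
  XtX <- crossprod(X)
  a0 <- spec$prior_tau_shape; b0 <- spec$prior_tau_rate
  prior_prec_beta <- diag(1 / spec$prior_beta_sd^2, p)
  gaussian <- spec$likelihood == "gaussian"

  keep_iter <- seq(spec$burnin + 1, spec$iter, by = spec$thin)
  S <- length(keep_iter)
  n_chains <- spec$chains

  beta_draws <- matrix(NA_real_, S * n_chains, p,
                       dimnames = list(NULL, colnames(X)))
  tau_phi_draws <- numeric(S * n_chains)
  tau_eps_draws <- numeric(S * n_chains)
  chain_id <- rep(seq_len(n_chains), each = S)
  ll_draws <- matrix(NA_real_, S * n_chains, n)
  phi_sum <- numeric(n)

  # Gauss-Hermite nodes for the marginal (overdispersion-integrated)
  # pointwise likelihood used by wAIC
  gh <- gauss_hermite(20)

  for (ch in seq_len(n_chains)) {
    with_seed(derive_seed(spec$seed, paste0("chain", ch)), {
      beta <- numeric(p)
      beta[1] <- log(mean(y) + 0.5) + rnorm(1, 0, 0.1)
      if (gaussian) beta[1] <- mean(y) + rnorm(1, 0, 0.1 * stats::sd(y))
      phi <- numeric(n)
      eta <- if (gaussian) NULL else log(y + 0.5) + rnorm(n, 0, 0.05)
      tau_phi <- tau_phi_fixed %||% 1
      tau_eps <- tau_eps_fixed %||% 1
      step <- rep(0.3, n)
      acc_n <- numeric(n)
      s_out <- 0L

      for (it in seq_len(spec$iter)) {
        mu_fix <- drop(X %*% beta)
        if (!gaussian) {
          # latent eta: vectorised adaptive random-walk Metropolis
          mu <- mu_fix + phi
          eta_star <- eta + step * rnorm(n)
          la <- y * (eta_star - eta) - (exp(eta_star) - exp(eta)) -
            0.5 * tau_eps * ((eta_star - mu)^2 - (eta - mu)^2)
          acc <- log(runif(n)) < la
          eta[acc] <- eta_star[acc]
          acc_n <- acc_n + acc
          if (it <= spec$burnin && it %% 50 == 0) {
            rate <- acc_n / 50
            step <- step * exp(0.3 * (rate - 0.44))
            acc_n[] <- 0
          }
          # joint level-shift move: translate eta and the intercept together
          # (the prior term cancels), curing slow mixing of the global level
          delta <- rnorm(1, 0, 0.03)
          la_s <- sum(y) * delta - (exp(delta) - 1) * sum(exp(eta)) -
            ((beta[1] + delta)^2 - beta[1]^2) / (2 * spec$prior_beta_sd^2)
          if (log(runif(1)) < la_s) {
            eta <- eta + delta
            beta[1] <- beta[1] + delta
          }
          z <- eta
        } else {
          z <- y
        }

        # beta | rest: conjugate Gaussian
        r <- z - phi
        Qb <- tau_eps * XtX + prior_prec_beta
        Rb <- chol(Qb)
        m <- backsolve(Rb, backsolve(Rb, tau_eps * crossprod(X, r),
                                     transpose = TRUE))
        beta <- drop(m + backsolve(Rb, rnorm(p)))
        mu_fix <- drop(X %*% beta)

        # phi | rest: chromatic single-site Gibbs, then recentred
        r2 <- z - mu_fix
        for (k in seq_along(cs_idx)) {
          cs <- cs_idx[[k]]
          if (length(cs) == 0) next
          nbsum <- as.numeric(cs_W[[k]] %*% phi)
          prec <- tau_phi * cs_nnb[[k]] + tau_eps
          mean_c <- (tau_phi * nbsum + tau_eps * r2[cs]) / prec
          phi[cs] <- rnorm(length(cs), mean_c, 1 / sqrt(prec))
        }
        if (any(non_island)) phi[non_island] <- phi[non_island] - mean(phi[non_island])

        # precisions | rest
        if (is.null(tau_phi_fixed) && nrow(el) > 0) {
          ssq_phi <- sum((phi[el[, 1]] - phi[el[, 2]])^2)
          tau_phi <- stats::rgamma(1, a0 + adjacency$icar_rank / 2,
                                   b0 + ssq_phi / 2)
        }
        if (is.null(tau_eps_fixed)) {
          eps <- z - mu_fix - phi
          tau_eps <- stats::rgamma(1, a0 + n / 2, b0 + sum(eps^2) / 2)
        }

        if (it > spec$burnin && ((it - spec$burnin) %% spec$thin == 0)) {
          s_out <- s_out + 1L
          row <- (ch - 1L) * S + s_out
          beta_draws[row, ] <- beta
          tau_phi_draws[row] <- tau_phi
          tau_eps_draws[row] <- tau_eps
          phi_sum <- phi_sum + phi
          mu <- mu_fix + phi
          if (gaussian) {
            ll_draws[row, ] <- stats::dnorm(y, mu, 1 / sqrt(tau_eps), log = TRUE)
          } else {
            # integrate the iid overdispersion out by Gauss-Hermite
            sd_e <- 1 / sqrt(tau_eps)
            lm <- vapply(seq_along(gh$nodes), function(q) {
              dpois(y, exp(mu + sqrt(2) * sd_e * gh$nodes[q]), log = TRUE) +
                log(gh$weights[q] / sqrt(pi))
            }, numeric(n))
            ll_draws[row, ] <- log_row_sum_exp(lm)
          }
        }
      }
    })
  }

  rhat <- c(
    apply(beta_draws, 2, function(v) split_rhat(v, chain_id)),
    tau_phi = split_rhat(tau_phi_draws, chain_id),
    tau_eps = split_rhat(tau_eps_draws, chain_id)
  )
  names(rhat)[seq_len(p)] <- colnames(X)
  fit <- structure(list(
    beta = beta_draws, tau_phi = tau_phi_draws, tau_eps = tau_eps_draws,
    chain_id = chain_id, phi_mean = phi_sum / (S * n_chains),
    ll = ll_draws, rhat = rhat,
    converged = all(is.finite(rhat)) && max(rhat) < 1.05,
    design = design, adjacency = adjacency
  ), class = "pd_car_fit")
  fit$waic <- waic(fit)
  fit
}

#' @export
print.pd_car_fit <- function(x, ...) {
  cat(sprintf("<pd_car_fit> %d draws x %d coefficients; wAIC %.1f; %s\n",
              nrow(x$beta), ncol(x$beta), x$waic$waic,
              if (x$converged) "converged" else
                sprintf("NOT converged (max R-hat %.3f)", max(x$rhat))))
  invisible(x)
}

# row-wise log-sum-exp of a matrix
log_row_sum_exp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# Gauss-Hermite nodes/weights (Golub-Welsch via the Jacobi matrix)
gauss_hermite <- function(k) {
  j <- sqrt(seq_len(k - 1) / 2)
  J <- diag(0, k)
  J[cbind(seq_len(k - 1), seq_len(k - 1) + 1)] <- j
  J[cbind(seq_len(k - 1) + 1, seq_len(k - 1))] <- j
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# split-R-hat of one parameter's draws over chains
split_rhat <- function(draws, chain_id) {
  halves <- lapply(split(draws, chain_id), function(v) {
    h <- floor(length(v) / 2)
    list(v[seq_len(h)], v[h + seq_len(h)])
  })
  segs <- unlist(halves, recursive = FALSE)
  m <- length(segs); nn <- length(segs[[1]])
  if (nn < 2) return(NA_real_)
  means <- vapply(segs, mean, 0)
  vars <- vapply(segs, var, 0)
  Wv <- mean(vars)
  Bv <- nn * var(means)
  if (Wv == 0) return(1)
  sqrt(((nn - 1) / nn * Wv + Bv / nn) / Wv)
}

#' Widely applicable information criterion
#'
#' `wAIC = -2 (lppd - p_waic)` computed from a pointwise log-likelihood
#' matrix (posterior draws in rows, observations in columns): `lppd` is the
#' sum over observations of the log of the mean pointwise likelihood over
#' draws, and `p_waic` the summed variance of the pointwise log-likelihoods.
#'
#' @param x a `pd_car_fit` or a draws-by-observations log-likelihood matrix.
#' @param ... unused.
#' @return list with `waic`, `lppd`, `p_waic`.
#' @export
waic <- function(x, ...) UseMethod("waic")

#' @rdname waic
#' @export
waic.pd_car_fit <- function(x, ...) waic(x$ll)

#' @rdname waic
#' @export
waic.matrix <- function(x, ...) {
  S <- nrow(x)
  lppd_i <- apply(x, 2, function(l) {
    mx <- max(l)
    mx + log(mean(exp(l - mx)))
  })
  # population variance over draws: invariant under duplicating the draws
  p_i <- apply(x, 2, function(l) mean((l - mean(l))^2))
  list(waic = -2 * (sum(lppd_i) - sum(p_i)),
       lppd = sum(lppd_i), p_waic = sum(p_i))
}

#' Posterior predicted richness over a pyrodiversity gradient
#'
#' Evaluates the linear predictor over a grid of pyrodiversity values,
#' holding every other covariate at its mean within the requested rainfall
#' stratum (and the spatial and overdispersion effects at zero), then
#' back-transforms through the link. Uncertainty comes from the posterior
#' draws.
#'
#' @param fit a [fit_car_model()] object.
#' @param pyro_grid pyrodiversity values (raw scale); defaults to an even
#'   grid over the stratum's observed range.
#' @param stratum `"wet"` or `"dry"`.
#' @param probs quantiles of the posterior band.
#' @return tibble with `pyrodiversity`, `median`, `lower`, `upper`.
#' @export
predicted_richness_curve <- function(fit, pyro_grid = NULL,
                                     stratum = c("wet", "dry"),
                                     probs = c(0.025, 0.975)) {
  stratum <- match.arg(stratum)
  design <- fit$design
  d <- design$cells
  in_str <- if (stratum == "wet") d$is_wet else !d$is_wet
  if (is.null(pyro_grid)) {
    rng <- range(d$pyrodiversity[in_str])
    pyro_grid <- seq(rng[1], rng[2], length.out = 50)
  }
  sc <- design$scaling
  ctr <- sc$center[sc$covariate == "pyrodiversity"]
  scl <- sc$scale[sc$covariate == "pyrodiversity"]
  pz <- (pyro_grid - ctr) / scl

  x0 <- colMeans(design$X[in_str, , drop = FALSE])
  Xn <- matrix(rep(x0, each = length(pyro_grid)), nrow = length(pyro_grid),
               dimnames = list(NULL, colnames(design$X)))
  col_lin <- paste0("pyrodiversity_", stratum)
  Xn[, col_lin] <- pz
  col_sq <- paste0("pyrodiversity_sq_", stratum)
  if (col_sq %in% colnames(Xn)) Xn[, col_sq] <- pz^2

  eta <- Xn %*% t(fit$beta)  # grid x draws
  pred <- if (fit$design$spec$likelihood == "poisson") exp(eta) else eta
  tibble(
    pyrodiversity = pyro_grid,
    median = apply(pred, 1, median),
    lower = apply(pred, 1, quantile, probs[1]),
    upper = apply(pred, 1, quantile, probs[2])
  )
}

#' Per-stratum effects table across fitted groups
#'
#' Summarises, for each fitted model and each fire covariate-by-stratum
#' coefficient: posterior median, 2.5% and 97.5% quantiles, and whether the
#' 95% credible interval excludes zero ("well supported").
#'
#' @param fits a named list of [fit_car_model()] objects (names = richness
#'   groups), or a single fit.
#' @return tibble with `group`, `covariate`, `stratum`, `median`, `lower`,
#'   `upper`, `supported`.
#' @export
effects_table <- function(fits) {
  if (inherits(fits, "pd_car_fit")) fits <- list(fit = fits)
  purrr::imap_dfr(fits, function(fit, nm) {
    cols <- grep("_(wet|dry)$", colnames(fit$beta), value = TRUE)
    cols <- setdiff(cols, "wet")
    purrr::map_dfr(cols, function(cl) {
      v <- fit$beta[, cl]
      q <- quantile(v, c(0.025, 0.5, 0.975))
      tibble(
        group = nm,
        covariate = sub("_(wet|dry)$", "", cl),
        stratum = sub(".*_(wet|dry)$", "\\1", cl),
        median = unname(q[2]), lower = unname(q[1]), upper = unname(q[3]),
        supported = unname(q[1] > 0 | q[3] < 0)
      )
    })
  })
}
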