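# small synthetic design for direct sampler checks
mini_design <- function(n_side = 10, y, X = NULL, likelihood = "poisson",
                        iter = 1500, seed = 1) {
  n <- n_side^2
  cells <- tibble::tibble(
    cell_row = rep(seq_len(n_side), each = n_side),
    cell_col = rep(seq_len(n_side), times = n_side),
    is_wet = rep(c(TRUE, FALSE), length.out = n),
    pyrodiversity = seq_len(n) / n)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  spec <- model_spec(fire_covariates = "pyrodiversity",
                     likelihood = likelihood, chains = 2, iter = iter,
                     burnin = iter / 2, seed = seed)
  structure(list(X = X, y = y, cells = cells,
                 scaling = tibble::tibble(covariate = character(0)),
                 n_dropped = 0, spec = spec), class = "pd_design")
}

test_that("an intercept-only fit recovers the analytic limit", {
  k <- 12
  des <- mini_design(n_side = 15, y = rep(k, 225), iter = 1500, seed = 2)
  fit <- fit_car_model(des)
  expect_lt(abs(median(fit$beta[, 1]) - log(k)), 0.05)
  # constant data: both random-effect SDs shrink small
  expect_lt(median(1 / sqrt(fit$tau_eps)), 0.2)
  expect_lt(abs(mean(fit$phi_mean)), 1e-8)  # ICAR sum-to-zero constraint
})

test_that("the Gaussian mode matches closed-form GLS with known precisions", {
  set.seed(5)
  n <- 100
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  beta_true <- c(2, 0.8, -0.5)
  y <- drop(X %*% beta_true) + rnorm(n, 0, 1)
  des <- mini_design(n_side = 10, y = y, X = X, likelihood = "gaussian",
                     iter = 3000, seed = 3)
  # spatial effect pinned to ~0 by a huge fixed precision
  fit <- fit_car_model(des, tau_phi_fixed = 1e8, tau_eps_fixed = 1)
  prior_prec <- diag(1 / 100, 3)
  want <- solve(crossprod(X) + prior_prec, crossprod(X, y))
  got <- colMeans(fit$beta)
  expect_lt(max(abs(got - drop(want)) / pmax(abs(want), 0.1)), 0.01)
})

test_that("wAIC follows its identities and an independent oracle", {
  set.seed(9)
  ll <- matrix(rnorm(50 * 20, -3, 0.4), 50, 20)
  # single draw: p_waic = 0, waic = -2 * lppd
  w1 <- waic(ll[1, , drop = FALSE])
  expect_equal(w1$p_waic, 0)
  expect_equal(w1$waic, -2 * sum(ll[1, ]))
  # duplicating every draw changes nothing
  expect_equal(waic(ll)$waic, waic(ll[rep(1:50, 2), ])$waic, tolerance = 1e-12)
  # independent direct-formula implementation
  oracle <- local({
    lppd <- sum(log(colMeans(exp(ll))))
    p <- sum(apply(ll, 2, function(v) sum((v - mean(v))^2) / length(v)))
    -2 * (lppd - p)
  })
  expect_equal(waic(ll)$waic, oracle, tolerance = 1e-6)
})

test_that("posterior summaries are invariant to cell ordering", {
  env <- test_env(10)
  tab <- build_cell_table(env)
  tab$pyrodiversity <- synthetic_pyrodiversity_surface(tab$map_mm, seed = 4)
  tab <- gen_richness(tab, make_truth(), seed = 4)
  tab$in_analysis <- tab$is_savanna
  spec <- model_spec(fire_covariates = "pyrodiversity", chains = 2,
                     iter = 1500, burnin = 750, seed = 6)
  f1 <- fit_car_model(build_design(tab, spec))
  set.seed(8)
  f2 <- fit_car_model(build_design(tab[sample.int(nrow(tab)), ], spec))
  m1 <- apply(f1$beta, 2, median)
  m2 <- apply(f2$beta, 2, median)[names(m1)]
  expect_lt(max(abs(m1 - m2)), 0.08)  # within Monte-Carlo error
})

test_that("80% intervals have sane empirical coverage at reduced size", {
  # simulation-based calibration, scaled down: 10 replicates x 50 cells
  hits <- 0; total <- 0
  for (r in 1:10) {
    n_side <- 8
    cells <- tibble::tibble(
      cell_id = 1:64,
      cell_row = rep(1:8, each = 8), cell_col = rep(1:8, times = 8),
      npp = runif(64, 0.2, 1.2), topo_het = runif(64, 5, 100),
      is_wet = rep(c(TRUE, FALSE), each = 32),
      in_analysis = TRUE)
    cells$pyrodiversity <- rnorm(64, 4, 1.5)
    truth <- make_truth(beta_pyro_wet = 0.09, beta_pyro_dry = 0.03,
                        spatial_sd = 0.1, od_sd = 0.1)
    cells <- gen_richness(cells, truth, seed = 700 + r)
    spec <- model_spec(fire_covariates = "pyrodiversity", chains = 2,
                       iter = 1200, burnin = 600, seed = 700 + r)
    fit <- fit_car_model(build_design(cells, spec))
    for (term in c("pyrodiversity_wet", "pyrodiversity_dry")) {
      tv <- if (term == "pyrodiversity_wet") 0.09 else 0.03
      ci <- quantile(fit$beta[, term], c(0.1, 0.9))
      hits <- hits + (ci[1] <= tv && tv <= ci[2])
      total <- total + 1
    }
  }
  cov <- hits / total
  expect_gte(cov, 0.60)
  expect_lte(cov, 0.95)
})

test_that("effects tables and predicted curves match draw-wise oracles", {
  # fabricated fit: known draws
  S <- 400
  set.seed(10)
  X <- cbind(`(Intercept)` = 1, topo_het = rnorm(30), wet = rep(0:1, 15),
             pyrodiversity_wet = rnorm(30), pyrodiversity_dry = rnorm(30))
  beta <- cbind(rnorm(S, 3, 0.01), rnorm(S, 0, 0.05), rnorm(S, 0.1, 0.05),
                rep(0.5, S), rnorm(S, 0, 0.2))
  colnames(beta) <- colnames(X)
  cells <- tibble::tibble(
    pyrodiversity = runif(30, 1, 7), is_wet = X[, "wet"] == 1)
  design <- structure(list(
    X = X, y = rpois(30, 20), cells = cells,
    scaling = tibble::tibble(covariate = "pyrodiversity", center = 4,
                             scale = 2),
    spec = model_spec(fire_covariates = "pyrodiversity")), class = "pd_design")
  fit <- structure(list(beta = beta, design = design), class = "pd_car_fit")

  et <- effects_table(list(toy = fit))
  expect_equal(nrow(et), 2)
  w <- et[et$stratum == "wet", ]
  expect_equal(w$median, 0.5)
  expect_equal(w$lower, 0.5)
  expect_true(w$supported)     # degenerate draws all 0.5
  d <- et[et$stratum == "dry", ]
  expect_equal(d$median, unname(quantile(beta[, "pyrodiversity_dry"], 0.5)))
  expect_false(d$supported)    # symmetric around zero

  # curve: constant positive effect is monotone; oracle quantiles
  cv <- predicted_richness_curve(fit, pyro_grid = c(2, 4, 6), stratum = "wet")
  expect_true(all(diff(cv$median) > 0))
  x0 <- colMeans(X[X[, "wet"] == 1, ])
  eta2 <- drop(beta %*% replace(x0, 4, (2 - 4) / 2))
  expect_equal(cv$median[1], median(exp(eta2)))
  expect_equal(cv$lower[1], unname(quantile(exp(eta2), 0.025)))

  # zero-effect curve is exactly flat
  beta0 <- beta; beta0[, 4] <- 0
  fit0 <- structure(list(beta = beta0, design = design), class = "pd_car_fit")
  cv0 <- predicted_richness_curve(fit0, pyro_grid = c(2, 4, 6), stratum = "wet")
  expect_equal(cv0$median, rep(cv0$median[1], 3))
})

test_that("unconverged fits are flagged, never hidden", {
  # two chains deliberately too short on hard data
  env <- test_env(10)
  tab <- build_cell_table(env)
  tab$pyrodiversity <- synthetic_pyrodiversity_surface(tab$map_mm, seed = 1)
  tab <- gen_richness(tab, make_truth(spatial_sd = 0.5), seed = 1)
  tab$in_analysis <- tab$is_savanna
  spec <- model_spec(fire_covariates = "pyrodiversity", chains = 2,
                     iter = 60, burnin = 30, seed = 1)
  fit <- fit_car_model(build_design(tab, spec))
  expect_type(fit$converged, "logical")
  expect_true(all(is.finite(fit$rhat)))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_s3_class(glance(fit), "tbl_df")
})
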