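#' Ground-truth parameters for the synthetic richness generator
#'
#' Collects the hidden parameters the recovery tests target: per-stratum
#' pyrodiversity effects (per SD of pyrodiversity, on the log-richness
#' scale), topography and NPP-response coefficients, optional per-attribute
#' and quadratic effects, overdispersion and spatial-field SDs. Defaults use
#' effect magnitudes of the size reported for continental savanna richness
#' (wet-stratum pyrodiversity effect about 0.09 per SD, dry about 0.03).
#'
#' @param beta0 intercept, log expected richness of an average cell.
#' @param beta_pyro_wet,beta_pyro_dry pyrodiversity effect per SD in wet and
#'   dry savanna.
#' @param beta_pyro2_wet,beta_pyro2_dry quadratic pyrodiversity effects.
#' @param beta_topo topographic-heterogeneity effect per SD.
#' @param beta_npp,beta_npp2 linear and quadratic NPP-response coefficients
#'   (the generator's smooth "spline shape").
#' @param beta_wet additive wet-savanna intercept shift.
#' @param attr_effects named numeric vector of per-attribute-mean effects
#'   (names among `mean_logarea`, `mean_fireday`, `mean_logfri`,
#'   `mean_logfrp`), per SD.
#' @param od_sd SD of the iid lognormal overdispersion.
#' @param spatial_sd SD of the smooth spatial field.
#' @param seed integer seed recorded with the truth.
#' @return object of class `pd_truth` (a named list).
#' @export
make_truth <- function(beta0 = log(30), beta_pyro_wet = 0.09,
                       beta_pyro_dry = 0.03, beta_pyro2_wet = 0,
                       beta_pyro2_dry = 0, beta_topo = 0.05,
                       beta_npp = 0.20, beta_npp2 = -0.04, beta_wet = 0.05,
                       attr_effects = c(mean_logarea = 0, mean_fireday = 0,
                                        mean_logfri = 0, mean_logfrp = 0),
                       od_sd = 0.15, spatial_sd = 0.15, seed = 1) {
  attr_effects <- unlist(attr_effects)  # tolerate a named list (JSON reload)
  structure(list(
    beta0 = beta0, beta_pyro_wet = beta_pyro_wet, beta_pyro_dry = beta_pyro_dry,
    beta_pyro2_wet = beta_pyro2_wet, beta_pyro2_dry = beta_pyro2_dry,
    beta_topo = beta_topo, beta_npp = beta_npp, beta_npp2 = beta_npp2,
    beta_wet = beta_wet, attr_effects = attr_effects,
    od_sd = od_sd, spatial_sd = spatial_sd, seed = seed
  ), class = "pd_truth")
}

#' Write and read ground truth as JSON
#' @param truth a [make_truth()] object.
#' @param path file path.
#' @return `read_truth()` returns a `pd_truth`.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$attr_effects <- as.list(x$attr_effects)  # keep names in the JSON object
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(make_truth, x)
}

#' A synthetic pyrodiversity surface for model tests
#'
#' For parameter-recovery experiments richness can be generated directly from
#' a pyrodiversity covariate without running the full fire pipeline. The
#' surface reproduces the observed continental pattern -- roughly flat below
#' 650 mm, declining above -- plus substantial cell-level noise so the
#' covariate is not spatially confounded with the smooth rainfall field.
#'
#' @param map_mm vector of cell MAP values.
#' @param seed integer seed.
#' @param noise_sd SD of the non-spatial component.
#' @return numeric vector, arbitrary positive index units.
#' @export
synthetic_pyrodiversity_surface <- function(map_mm, seed = 1, noise_sd = 1) {
  with_seed(derive_seed(seed, "pyro_surface"), {
    base <- 4 - 2.5 * pmin(pmax((map_mm - 650) / 750, 0), 1)
    pmax(0, base + rnorm(length(map_mm), 0, noise_sd))
  })
}

#' Generate per-cell richness counts with known effects
#'
#' Draws counts from the same family the spatial model fits: a
#' Poisson-lognormal with log-link linear predictor combining the NPP
#' response, topographic heterogeneity, a wet-savanna intercept shift,
#' wet/dry-specific (and optionally quadratic) pyrodiversity effects,
#' optional per-attribute-mean effects, a smooth spatial field and iid
#' overdispersion. Continuous covariates are z-scored over the supplied
#' cells, matching the standardisation the model applies, so the truth's
#' coefficients are directly comparable to fitted ones.
#'
#' @param cells tibble with `cell_row`, `cell_col`, `is_wet`, `npp`,
#'   `topo_het`, `pyrodiversity` (and any attribute-mean columns named in
#'   `truth$attr_effects` with nonzero effect).
#' @param truth a [make_truth()] object.
#' @param seed integer seed.
#' @return `cells` with added columns `eta_true`, `spatial_true` and
#'   `richness_sim` (integer counts).
#' @export
gen_richness <- function(cells, truth, seed = 1) {
  stopifnot(inherits(truth, "pd_truth"))
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  with_seed(derive_seed(seed, "richness"), {
    pyro_z <- zs(cells$pyrodiversity)
    npp_z <- zs(cells$npp)
    topo_z <- zs(cells$topo_het)
    wet <- as.numeric(cells$is_wet)
    eta <- truth$beta0 +
      truth$beta_npp * npp_z + truth$beta_npp2 * npp_z^2 +
      truth$beta_topo * topo_z + truth$beta_wet * wet +
      (truth$beta_pyro_wet * wet + truth$beta_pyro_dry * (1 - wet)) * pyro_z +
      (truth$beta_pyro2_wet * wet + truth$beta_pyro2_dry * (1 - wet)) * pyro_z^2
    for (a in names(truth$attr_effects)) {
      b <- truth$attr_effects[[a]]
      if (b != 0) eta <- eta + b * zs(cells[[a]])
    }
    if (truth$spatial_sd > 0) {
      nr <- max(cells$cell_row); nc <- max(cells$cell_col)
      f <- gaussian_field(nr, nc, range_cells = max(2, nr / 6)) * truth$spatial_sd
      sp <- f[cbind(cells$cell_row, cells$cell_col)]
    } else sp <- rep(0, nrow(cells))
    eta <- eta + sp + rnorm(nrow(cells), 0, truth$od_sd)
    if (any(eta > 20)) abort("linear predictor overflow (> exp(20)): mis-parameterised truth")
    cells$eta_true <- eta
    cells$spatial_true <- sp
    cells$richness_sim <- rpois(nrow(cells), exp(eta))
    cells
  })
}

#' Generate species range polygons and a trait table
#'
#' Places rectangular species ranges whose centres are sampled proportionally
#' to a per-cell richness target, with lognormal range widths, so the
#' richness implied by polygon overlap tracks the target surface (rank
#' correlation above 0.8 at defaults). Body masses are lognormal and about
#' 20% of mammal species are flagged as bats.
#'
#' @param env a [gen_environment()] stack.
#' @param richness_target per-cell target (any positive scale; only its
#'   spatial pattern matters).
#' @param n_species number of species to place.
#' @param taxon "mammal" or "bird" (controls trait columns).
#' @param concentration exponent applied to the target when sampling range
#'   centres; values above 1 compensate for the spatial smearing of
#'   multi-cell ranges (4 keeps the implied-richness rank correlation above
#'   0.8 at the default grid and species count).
#' @param seed integer seed.
#' @return list with `ranges` (polygon tibble) and `traits` (tibble with
#'   `species_id`, `taxon`, `body_mass_kg`, `is_bat`).
#' @export
gen_species_ranges <- function(env, richness_target, n_species = 150,
                               taxon = "mammal", concentration = 4, seed = 1) {
  stopifnot(inherits(env, "pd_env"), length(richness_target) == nrow(env$cells))
  if (n_species == 0) {
    return(list(
      ranges = tibble(poly_id = character(0), x = numeric(0), y = numeric(0)),
      traits = tibble(species_id = character(0), taxon = character(0),
                      body_mass_kg = numeric(0), is_bat = logical(0))
    ))
  }
  with_seed(derive_seed(seed, paste0("ranges_", taxon)), {
    cells <- env$cells
    w <- pmax(richness_target, 0)^concentration
    w <- if (sum(w) == 0) rep(1, length(w)) else w / sum(w)
    ctr <- sample.int(nrow(cells), n_species, replace = TRUE, prob = w)
    hw_x <- exp(rnorm(n_species, log(1.0 * env$grid$cell_deg), 0.45))
    hw_y <- exp(rnorm(n_species, log(1.0 * env$grid$cell_deg), 0.45))
    ids <- sprintf("%s_%03d", substr(taxon, 1, 3), seq_len(n_species))
    ranges <- purrr::map_dfr(seq_len(n_species), function(s) {
      cx <- cells$lon_c[ctr[s]] + runif(1, -0.3, 0.3) * env$grid$cell_deg
      cy <- cells$lat_c[ctr[s]] + runif(1, -0.3, 0.3) * env$grid$cell_deg
      r <- rect_ring(cx - hw_x[s], cx + hw_x[s], cy - hw_y[s], cy + hw_y[s])
      tibble(poly_id = ids[s], x = r[, 1], y = r[, 2])
    })
    bat <- if (identical(taxon, "mammal")) runif(n_species) < 0.2 else
      rep(FALSE, n_species)
    traits <- tibble(
      species_id = ids, taxon = taxon,
      body_mass_kg = exp(rnorm(n_species, log(1), 1.8)),
      is_bat = bat
    )
    list(ranges = ranges, traits = traits)
  })
}
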