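---
title: "Pyrodiversity and richness: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pyrodiversity and richness: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(pyrodiv)
library(dplyr)
```

## The scientific problem

Savanna fire regimes differ not only in how much they burn but in how
*variable* their fires are. "Pyrodiversity" summarises that variability: a
region whose fires span many sizes, seasons, return intervals and intensities
offers a wider range of post-fire habitats than one burning on a fixed
schedule, and the long-standing hypothesis is that this variety begets
biodiversity. Testing the idea at continental scale needs three ingredients
that this package implements end to end:

1. **Fire delineation** -- individual fires reconstructed from per-pixel burn
   dates by spatiotemporal flood fill, each carrying four attributes:
   `logArea` (ln km^2), `fireday` (signed days between ignition and the 15th
   of the locally wettest month), `logFRI` (ln mean days since the previous
   burn of the fire's pixels) and `logFRP` (ln mean radiative power, MW, from
   joined active-fire detections).
2. **A pyrodiversity index** -- per grid cell, the volume of the minimum
   convex hull of its fires in the 4-dimensional attribute space after global
   SD-normalisation, bias-corrected by a nonparametric bootstrap.
3. **Spatial richness models** -- Bayesian Poisson regressions of bird and
   mammal richness on pyrodiversity with wet/dry rainfall interactions, an
   NPP spline, topographic heterogeneity, and an intrinsic CAR spatial field,
   compared by wAIC; plus random-intercept contrasts of fire attributes
   inside versus outside protected areas.

Real inputs (satellite burned-area and active-fire products, gridded
climatologies, range maps, protected-area polygons) are continental-scale
downloads. The package therefore ships a synthetic-landscape generator with
recorded ground truth, so every stage is exercisable and testable at desk
scale.

## The synthetic landscape

`gen_environment()` builds rainfall, elevation and NPP surfaces on a planar
grid (default 20 x 20 cells of 0.5 degrees, 10 x 10 pixels per cell, with
pixel areas carried explicitly in km^2 so no geodesy is needed). Mean annual
precipitation (MAP) is a smooth Gaussian random field whose marginal is
rank-mapped to span 300-1400 mm exactly: the rank mapping keeps the wet
(> 650 mm) and dry strata reasonably balanced (roughly a third of cells dry)
while preserving spatial smoothness. NPP is a saturating monotone function
of MAP plus noise, so their positive rank correlation holds by construction.

`fire_regime()` encodes what makes the synthetic world scientifically
interesting: above the 650 mm threshold, fire frequency and -- more
importantly for a hull volume -- the *dispersion* of fire attributes (size
spread, season spread, intensity spread) decline with rainfall, while fire
timing concentrates in the local dry season about half a year after the rain
peak. Fires are grown by stochastic region-growing from ignition pixels with
burn dates advancing over a spread window of at most 8 days, so multi-day
fires exist and exercise the date-gap rule. The emergent pattern -- highest
pyrodiversity in dry savannas, declining above 650 mm -- is a qualitative
reproduction of the continental pattern; no quantitative fire-size or
intensity distributions are published for it, so the lognormal defaults are
the package's own choices, exposed as parameters.

```{r fig1b, eval = FALSE}
g <- pd_grid(16, 16)
env <- gen_environment(g, seed = 1)
fh <- gen_fire_history(env, years = 10, seed = 1)
fires <- delineate_fires(fh$burn) |>
  attach_frp(fh$detections, g) |>
  assemble_fire_table(fh$burn, env$cells)
cells <- build_cell_table(env, cell_fires = cell_summaries(fires, seed = 1))
plot_cell_map(cells, pyrodiversity)
```

What the generator does *not* emulate matters for interpreting green tests:
there are no sensor artefacts beyond a uniform detection rate (no cloud
gaps, no false alarms), ranges are convex rectangles rather than ragged
IUCN-style polygons, and richness is generated from the same model family
the fit assumes. Passing recovery tests therefore demonstrates that the
estimation machinery is correct and well calibrated -- not that the model is
robust to the misspecification real data would bring.

## Fire delineation choices

Two burned pixel-observations belong to one fire exactly when a chain of
observations connects them, each link spatially adjacent (8-connectivity by
default) with burn dates at most 8 days apart. Both constants are arguments:
the source analyses delegate them to the burned-area product's compositing
behaviour, so they are flagged as assumptions here. Notable consequences of
the chain rule: fires may last longer than the gap (links, not spans, are
bounded), and a pixel burning in different years contributes separate
observations to separate fires.

`fireday` uses the real calendar (all dates are integer days since
2000-01-01), returns the minimal signed circular difference in [-182, +183],
positive after the rainfall peak, and prefers +183 on an exact half-year tie.
`logFRI` is undefined -- a value, not an error -- when no pixel of a fire has
an earlier burn; following the source's join rule, fires lacking either FRI
or an FRP match are excluded from the fire table, with exclusion counts
recorded as an attribute.

A detection joins a fire when it falls in the fire's pixel footprint within
a +/-2-day pad of the fire's date span; a detection matching two fires goes
to the nearer date window, ties to the earlier fire id. Cell assignment of a
fire is by footprint centroid, so each fire is counted once.

## The pyrodiversity index

Attributes are SD-normalised *globally* (one SD per attribute over all
fires), not per cell -- otherwise cell volumes would not be comparable
across the map. The hull volume is computed by an incremental
beneath-beyond construction in compiled code, exact for polytopes (unit
hypercube = 1, unit 4-simplex = 1/24) and verified against Monte-Carlo
membership oracles; degenerate inputs (fewer than 5 points, affine
dependence) have volume 0 by contract.

Because the hull of a sample underestimates the support of the underlying
distribution, and cells hold very different fire counts, the raw volume is
corrected by the standard additive bootstrap bias correction
`max(0, 2 V_obs - mean(V_boot))` with B = 200 resamples. The source names
only "a nonparametric bootstrap to correct volume for sample size", so the
exact scheme is an assumption; a rarefaction mode (average hull volume of
fixed-size subsamples) is available behind a flag for sensitivity checks.
Cells with fewer than `n_min = 10` fires get a missing index -- 4D hulls on
fewer points are dominated by degeneracy -- but keep their attribute means.

CV definitions need care because a CV of a signed or logged quantity is
ill-defined: area, FRI and FRP CVs are taken on their positive raw scales
(km^2, days, MW), and season variability is the circular SD of ignition
day-of-year divided by 365. Bootstrap resampling is seeded per cell from
`(seed, cell_id)` with fires in id order, making the whole index invariant
to row order of the fire table.

## The richness model

Counts are modelled as Poisson with log link:

```
log mu_i = x_i' beta + phi_i + eps_i
```

with `phi` an intrinsic CAR (Besag) field on queen adjacency under a
sum-to-zero constraint, `eps` iid Gaussian overdispersion, Normal(0, 10^2)
priors on fixed effects, and Gamma(0.1, 0.5) priors on both random-effect
precisions (equivalently log-gamma on the log precisions -- effectively flat
over the relevant range). The design holds an intercept, a cubic B-spline of
standardised NPP with two interior knots at its terciles ("two knots" fixes
neither placement nor degree, so both are documented choices), standardised
topographic heterogeneity (SD of pixel elevation -- the metric itself is an
assumption, as no source DEM or definition is stated), a wet indicator, and
one `_wet`/`_dry` column pair per fire covariate. That stratified
parameterisation gives per-stratum effects directly, matching how
wet-versus-dry coefficient tables are reported; a continuous
rainfall-interaction variant was considered and rejected as the default
because the reported tables are stratified. Means and CVs of the attributes
are never mixed in one model (they are strongly correlated); `model_class`
selects the set.

Inference is by Metropolis-within-Gibbs rather than a nested-Laplace
approximation: the contract is posterior quantiles, not a particular
approximation algorithm. The latent `eta` gets vectorised adaptive
random-walk updates (its full conditionals are independent across cells),
plus a joint level-shift move translating `eta` and the intercept together,
which cures the slow global-level mixing typical of centred
parameterisations; `beta` and `phi` have conjugate Gaussian updates (`phi`
via chromatic Gibbs on the 4-colouring of the queen lattice); precisions are
conjugate Gamma. Defaults are 2 chains of 4000 iterations, half burn-in.
Convergence is summarised by split-R-hat on all fixed effects and precisions
with a 1.05 threshold; an unconverged fit is returned flagged, never
silently. Island cells (no neighbours) keep a zero spatial effect.
The likelihood family itself is a documented choice -- the source states
none -- and a Gaussian mode for continuous responses sits behind a flag,
fitted by fully conjugate Gibbs.

wAIC is computed as `-2 (lppd - p_waic)` from pointwise likelihoods that
integrate the iid overdispersion out by 20-point Gauss-Hermite quadrature
(conditioning on the spatial field, as is standard for spatial models). Had
the pointwise likelihood conditioned on the latent `eta` instead, every
model would fit the data almost equally well through its own latent values
and the criterion could not separate model classes; the marginal form
restores that discrimination, and simulation tests confirm it prefers the
generating class. `p_waic` uses the population variance over draws, which
(unlike the sample variance) is exactly invariant to duplicating draws.

### Problem sizes in the tests

Simulation tests run at sizes chosen to make their statistical claims
meaningful while staying desk-scale: parameter recovery uses 20 replicates
of a 20 x 20 grid (400 cells) with 2 chains of 2500 iterations; model
selection uses 20 replicates per truth at 14 x 14; the calibration check
runs 10 replicates of 64 cells; the bootstrap bias study uses 100 replicates
at n = 20, 50, 100 with B = 200. The recovery truths (wet effect 0.09, dry
0.03 per SD of pyrodiversity) use the magnitude reported for continental
savanna mammal richness, and recovery is judged by 95% credible-interval
coverage and by the wet-stratum median exceeding the dry one.

## Protected-area contrast

`build_buffer_table()` compares cells at least 50%-covered by a protected
area ("covered by at least 50% of the protected-area polygon" is read as
cell-coverage-by-PA, consistent with confining the richness analysis to
protected cells; the threshold is an argument) against non-PA cells with at
least 20% of their area within a 100 km buffer, excluding cells inside any
other PA -- whether the original buffers excluded other PAs' interiors is
unstated, so exclusion is the package's default. Distances are planar, using
the grid's km-per-degree metadata. Each metric is then fitted with a
Gaussian random intercept per PA by profile REML: the variance ratio is
profiled out with closed-form groupwise GLS and optimised numerically, which
a grid-search bound verifies to 1e-6 in the tests; the implementation is
cross-checked against `lme4::lmer` to 4 decimals. Singular fits (group
variance at zero) are returned flagged.

## Numerical and degenerate-input conventions

- Hull tolerance is `1e-10 * (1 + max |coordinate|)`; points on a facet plane
  are treated as not visible, which cannot change the volume.
- `hull_volume()` returns 0 (not an error) for degenerate clouds;
  `bootstrap_corrected_volume()` returns `NA` below 5 points and floors the
  corrected volume at 0.
- Zero-variance attributes abort normalisation by name; zero-variance
  covariates abort the design build.
- Climate peak-month ties resolve to the earliest month; the wet threshold
  is strict (`> 650`); trait medians are inclusive-low for body mass (small)
  and inclusive-high for range size (common), so an all-equal-mass pool
  degenerates to "all small", documented and tested.
- Cell polygons are half-open `[west, east) x [south, north)`, so cells tile
  without double counting; `cell_id` is row-major from the north-west origin.
- All randomness flows through explicit seeds; generators derive child seeds
  from `(seed, purpose)` so adding a stage never perturbs another stage's
  stream, and the end-to-end pipeline is bit-reproducible.

## Known limitations

- The index is the hull volume only; kernel hypervolumes or functional
  richness variants are out of scope.
- The CAR model conditions on the wet/dry factor rather than continuous
  rainfall by default; both the likelihood family and the bootstrap scheme
  are assumptions where the source is silent, and are exposed as options.
- Synthetic ranges and protected areas are rectangles; polygon handling is
  exact for convex rings only.
- Recovery tests validate the machinery under the generator's assumptions;
  they cannot certify behaviour under real-data misspecification (sensor
  artefacts, non-Poisson dispersion, range-map error).
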