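# pyrodiv

Pyrodiversity indices and rainfall-contingent richness models for savanna
fire regimes.

## What this package is for

Savanna fires differ in size, season, return interval and intensity, and the
variability among fires within a region — its **pyrodiversity** — has long
been proposed as a driver of biodiversity. `pyrodiv` implements a complete
desk-scale pipeline for testing that hypothesis the way it is tested at
continental scale:

- **Fire delineation.** Individual fires are reconstructed from per-pixel
  burn-date rasters by spatiotemporal flood fill: two burned
  pixel-observations belong to one fire iff a chain of spatially adjacent
  observations links them with pairwise date differences within a gap
  (defaults: 8-connectivity, 8 days). Each fire carries four attributes —
  `logArea` (ln km²), `fireday` (signed days between ignition and the 15th of
  the locally wettest month), `logFRI` (ln mean days since each pixel's
  previous burn) and `logFRP` (ln mean radiative power from joined
  active-fire detections). Fires lacking FRI or an FRP match are excluded.

- **Pyrodiversity index.** Every fire is a point in the 4-dimensional
  attribute space. After dividing each attribute by its global standard
  deviation, the pyrodiversity of a grid cell is the volume of the minimum
  convex hull of its fires, corrected for sample size by a nonparametric
  bootstrap (`max(0, 2·V_obs − mean(V_boot))`, B = 200). The hull is computed
  by an incremental beneath-beyond algorithm in compiled code.

- **Spatial richness models.** Bird/mammal richness per quarter-degree-style
  cell is modelled as Poisson with log link,

  `log μ_i = x_i'β + φ_i + ε_i`,

  where `x_i` holds a cubic B-spline of NPP (two interior knots), topographic
  heterogeneity, a wet-savanna indicator (> 650 mm mean annual rainfall) and
  wet/dry-stratified fire covariates (pyrodiversity plus either the four
  attribute means or the four CVs); `φ` is an intrinsic CAR (Besag) spatial
  effect on queen adjacency with Gamma(0.1, 0.5) precision priors, and `ε`
  is iid overdispersion. Inference is Metropolis-within-Gibbs MCMC; models
  are compared by wAIC and effects judged by 95% credible intervals.

- **Protected-area contrasts.** Fire metrics inside PAs (cells ≥ 50%
  covered) are compared with cells in 100-km buffers (≥ 20% inclusion) via
  Gaussian random-intercept models fitted by profile REML.

- **Synthetic landscapes.** Because the real inputs are continental
  satellite and range-map downloads, a first-class generator module emulates
  all of them — rainfall/NPP/elevation surfaces, multi-year fire histories
  with detections, species ranges with traits, protected areas — with
  recorded ground truth, so the full pipeline runs and is tested end to end
  from code alone.

## Worked example

Simulate a landscape, run the fire pipeline, and summarise the index:

```r
library(pyrodiv)
library(dplyr)

g   <- pd_grid(16, 16)                       # 16 x 16 cells, 10 x 10 pixels each
env <- gen_environment(g, seed = 1)          # rainfall, NPP, elevation
fh  <- gen_fire_history(env, years = 10, seed = 1)

fires <- delineate_fires(fh$burn, connectivity = 8, date_gap_days = 8) |>
  attach_frp(fh$detections, g) |>
  assemble_fire_table(fh$burn, env$cells)

cells <- build_cell_table(env,
  cell_fires = cell_summaries(fires, B = 200, seed = 1))

cells |>
  filter(!is.na(pyrodiversity)) |>
  group_by(stratum = ifelse(is_wet, "wet (>650 mm)", "dry (<650 mm)")) |>
  summarise(cells = n(), median_pyrodiversity = median(pyrodiversity),
            median_fires = median(n_fires))
#> # A tibble: 2 × 4
#>   stratum       cells median_pyrodiversity median_fires
#>   <chr>         <int>                <dbl>        <dbl>
#> 1 dry (<650 mm)    82                 37.9         30
#> 2 wet (>650 mm)    92                 22.1         17.5
```

Pyrodiversity is highest in the dry savanna and declines with rainfall above
650 mm — the continental pattern the generator is built to reproduce. Fitting
the richness model to data generated with known wet/dry pyrodiversity
effects (0.09 and 0.03 per SD):

```r
tab <- build_cell_table(gen_environment(pd_grid(20, 20), seed = 2))
tab$pyrodiversity <- synthetic_pyrodiversity_surface(tab$map_mm, seed = 2)
tab <- gen_richness(tab, make_truth(beta_pyro_wet = 0.09, beta_pyro_dry = 0.03),
                    seed = 2)
tab$in_analysis <- tab$is_savanna

fit <- fit_car_model(build_design(tab,
  model_spec(fire_covariates = "pyrodiversity", chains = 2, iter = 3000,
             burnin = 1500, seed = 2)))
fit
#> <pd_car_fit> 3000 draws x 10 coefficients; wAIC 2717.1; converged
tidy(fit) |> filter(grepl("pyrodiversity", term))
#>                term estimate conf.low conf.high rhat supported
#> 1 pyrodiversity_wet   0.1154    0.076     0.156    1      TRUE
#> 2 pyrodiversity_dry  -0.0015   -0.070     0.072    1     FALSE
```

Both 95% credible intervals cover their truths; the wet-savanna effect is
well supported (interval excludes zero) while the small dry effect is not —
the rainfall-contingent pattern the model class is designed to expose.
`autoplot(fit)`, `plot_cell_map(cells, pyrodiversity)` and
`predicted_richness_curve(fit)` visualise effects, maps and curves;
`waic(fit)`, `glance(fit)` and `effects_table()` summarise fits;
`build_buffer_table()` + `contrast_report()` run the protected-area
contrast. A thin command-line front end over the same functions lives at
`inst/cli/pyrodiv.R` (subcommands `simulate`, `fires`, `index`, `grid`,
`fit`, `contrast`).

## Package layout

- `R/` — generators (`gen_*`), fire events (`delineate_fires`,
  `compute_fireday`, `compute_fri`, `attach_frp`, `assemble_fire_table`),
  index (`normalise_attributes`, `hull_volume`,
  `bootstrap_corrected_volume`, `cell_summaries`), covariates
  (`build_cell_table` and friends), models (`model_spec`, `build_design`,
  `fit_car_model`, `waic`, `effects_table`), PA contrast
  (`build_buffer_table`, `fit_random_intercept`, `contrast_report`), plots
  and broom-style tidiers.
- `src/` — the d-dimensional convex hull and the spatiotemporal flood fill.
- `vignettes/pyrodiversity-methods.Rmd` — the model, its assumptions, every
  tunable parameter, and the design decisions.
- `tests/testthat/` — unit, property and simulation tests, including
  independent brute-force oracles for every geometric and combinatorial
  primitive.
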