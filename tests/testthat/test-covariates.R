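test_that("climate summaries follow the tie and threshold rules", {
  # all months equal: peak month resolves to January
  expect_equal(summarise_climate(rep(50, 12)),
               tibble::tibble(map_mm = 600, peak_month = 1L),
               ignore_attr = TRUE)
  one <- rep(0, 12); one[1] <- 200
  sc <- summarise_climate(one)
  expect_equal(sc$map_mm, 200)
  expect_equal(sc$peak_month, 1L)
  # wet/dry threshold is strict at 650
  m660 <- matrix(rep(c(660, 640) / 12, each = 12), ncol = 12, byrow = TRUE)
  sc2 <- summarise_climate(m660)
  expect_equal(sc2$map_mm > 650, c(TRUE, FALSE))
})

test_that("NPP means ignore missing pixels and match a flat-mean oracle", {
  g <- pd_grid(5, 5, pixels_per_cell = 2)
  const <- matrix(0.7, g$px_rows, g$px_cols)
  expect_equal(mean_npp(list(const), g), rep(0.7, 25))
  two <- list(matrix(1, g$px_rows, g$px_cols), matrix(3, g$px_rows, g$px_cols))
  expect_equal(mean_npp(two, g), rep(2, 25))

  set.seed(2)
  stack <- lapply(1:3, function(i) {
    m <- matrix(runif(g$px_rows * g$px_cols), g$px_rows)
    m[sample(length(m), 10)] <- NA
    m
  })
  got <- mean_npp(stack, g)
  # oracle: per-pixel mean over years, then cell means, NA excluded
  px <- Reduce(`+`, lapply(stack, function(m) ifelse(is.na(m), 0, m))) /
    Reduce(`+`, lapply(stack, function(m) !is.na(m)))
  for (cid in c(1, 7, 25)) {
    cr <- (cid - 1) %/% 5 + 1; cc <- (cid - 1) %% 5 + 1
    block <- px[(cr - 1) * 2 + 1:2, (cc - 1) * 2 + 1:2]
    expect_equal(got[cid], mean(block, na.rm = TRUE))
  }
})

test_that("topographic heterogeneity is the within-cell SD of elevation", {
  g <- pd_grid(5, 5, pixels_per_cell = 2)
  flat <- matrix(100, g$px_rows, g$px_cols)
  expect_equal(topo_heterogeneity(flat, g), rep(0, 25))
  two_level <- flat
  two_level[, seq(1, g$px_cols, by = 2)] <- 0   # half pixels 0, half 100
  got <- topo_heterogeneity(two_level, g)
  expect_equal(got, rep(sd(c(0, 0, 100, 100)), 25))
  set.seed(3)
  rnd <- matrix(rnorm(g$px_rows * g$px_cols, 500, 80), g$px_rows)
  got <- topo_heterogeneity(rnd, g)
  block <- rnd[1:2, 1:2]
  expect_equal(got[1], sd(block))
})

test_that("PA coverage matches containment cases and a subpixel oracle", {
  g <- pd_grid(6, 6)
  cells <- grid_cells(g)
  # PA containing cell 1 entirely
  big <- tibble::tibble(poly_id = "p", x = c(19, 22, 22, 19), y = c(-2, -2, 1, 1))
  cov <- pa_coverage(cells, big)
  expect_equal(cov[1], 1)
  # disjoint
  far <- tibble::tibble(poly_id = "p", x = c(50, 51, 51, 50), y = c(50, 50, 51, 51))
  expect_equal(pa_coverage(cells, far), rep(0, 36))

  # random rectangles vs 200 x 200 subpixel count
  set.seed(11)
  for (r in 1:5) {
    x0 <- runif(1, 19.5, 22); y0 <- runif(1, -3, -1)
    w <- runif(1, 0.2, 1.5); h <- runif(1, 0.2, 1.5)
    pa <- tibble::tibble(poly_id = "p", x = c(x0, x0 + w, x0 + w, x0),
                         y = c(y0, y0, y0 + h, y0 + h))
    cov <- pa_coverage(cells, pa)
    i <- which.max(cov)
    gx <- seq(cells$lon_min[i], cells$lon_max[i], length.out = 201)[-1] -
      (cells$lon_max[i] - cells$lon_min[i]) / 400
    gy <- seq(cells$lat_min[i], cells$lat_max[i], length.out = 201)[-1] -
      (cells$lat_max[i] - cells$lat_min[i]) / 400
    pts <- expand.grid(x = gx, y = gy)
    frac <- mean(pts$x >= x0 & pts$x <= x0 + w & pts$y >= y0 & pts$y <= y0 + h)
    expect_equal(cov[i], frac, tolerance = 0.01)
  }
})

test_that("richness rasterisation equals a brute-force intersection oracle", {
  g <- pd_grid(6, 6)
  cells <- grid_cells(g)
  set.seed(13)
  polys <- purrr::map_dfr(1:12, function(s) {
    x0 <- runif(1, 19, 22.5); y0 <- runif(1, -3.5, 0)
    w <- runif(1, 0.3, 2); h <- runif(1, 0.3, 2)
    tibble::tibble(poly_id = sprintf("s%02d", s),
                   x = c(x0, x0 + w, x0 + w, x0), y = c(y0, y0, y0 + h, y0 + h))
  })
  got <- rasterise_richness(polys, cells)
  rings <- pyrodiv:::polys_to_rings(polys)
  for (i in seq_len(nrow(cells))) {
    n <- 0
    for (ring in rings) {
      bx <- range(ring[, 1]); by <- range(ring[, 2])
      ox <- max(0, min(bx[2], cells$lon_max[i]) - max(bx[1], cells$lon_min[i]))
      oy <- max(0, min(by[2], cells$lat_max[i]) - max(by[1], cells$lat_min[i]))
      if (ox * oy > 1e-12) n <- n + 1
    }
    expect_identical(got$richness[i], as.integer(n))
  }
  expect_true(all(rasterise_richness(polys[0, ], cells)$richness == 0))
})

test_that("trait partitions follow the documented tie rules", {
  tr <- tibble::tibble(
    species_id = paste0("m", 1:4), taxon = "mammal",
    body_mass_kg = c(1, 2, 3, 4), is_bat = FALSE,
    range_size_cells = c(1, 5, 5, 9))
  p <- partition_species(tr)
  expect_equal(p$grp_small, c(TRUE, TRUE, FALSE, FALSE))   # mass <= median
  expect_equal(p$grp_large, !p$grp_small)
  expect_equal(p$grp_common, c(FALSE, TRUE, TRUE, TRUE))    # size >= median
  # degenerate: all equal masses -> small = all, large = empty
  tr$body_mass_kg <- 2
  p2 <- partition_species(tr)
  expect_true(all(p2$grp_small))
  expect_false(any(p2$grp_large))
})

test_that("richness partitions add up and the analysis set is monotone", {
  env <- test_env(12, seed = 7)
  tab0 <- build_cell_table(env)
  target <- exp(log(30) + 0.3 * (tab0$npp - mean(tab0$npp)) / sd(tab0$npp))
  mam <- gen_species_ranges(env, target, n_species = 80, taxon = "mammal",
                            seed = 3)
  brd <- gen_species_ranges(env, target, n_species = 60, taxon = "bird",
                            seed = 4)
  ranges <- dplyr::bind_rows(mam$ranges, brd$ranges)
  traits <- dplyr::bind_rows(mam$traits, brd$traits)
  pa <- gen_protected_areas(env, n_pa = 5, seed = 3)
  tab <- build_cell_table(env, pa_polys = pa, range_polys = ranges,
                          traits = traits)
  expect_true(all(tab$richness_bats + tab$richness_mammals_nobats ==
                    tab$richness_mammals_all))
  expect_true(all(tab$richness_mammals_small + tab$richness_mammals_large ==
                    tab$richness_mammals_all))
  expect_true(all(tab$richness_mammals_common <= tab$richness_mammals_all))
  expect_true(all(tab$richness_birds_common <= tab$richness_birds_all))
  expect_true(all(tab$in_analysis == (tab$is_savanna & tab$pa_fraction >= 0.5)))
  expect_true(all(tab$is_wet == (tab$map_mm > 650)))
  # raising the coverage threshold never adds analysis cells
  t40 <- build_cell_table(env, pa_polys = pa, pa_threshold = 0.4)
  t60 <- build_cell_table(env, pa_polys = pa, pa_threshold = 0.6)
  expect_true(all(which(t60$in_analysis) %in% which(t40$in_analysis)))
})
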