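# shared fixtures and independent oracles, all built in code

# a small deterministic environment, memoised per (n, seed)
test_env <- local({
  cache <- list()
  function(n = 10, seed = 42) {
    key <- paste(n, seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- gen_environment(pd_grid(n, n), seed = seed)
    }
    cache[[key]]
  }
})

# random burn history on a small pixel grid: n_obs observations with
# possibly repeated pixels across layers
random_burn <- function(px = 8, n_obs = 30, n_layers = 3, date_range = 60,
                        seed = 1) {
  set.seed(seed)
  grid <- pd_grid(5, 5, pixels_per_cell = ceiling(px / 5))
  layers <- lapply(seq_len(n_layers), function(k)
    matrix(NA_integer_, grid$px_rows, grid$px_cols))
  for (i in seq_len(n_obs)) {
    k <- sample.int(n_layers, 1)
    r <- sample.int(grid$px_rows, 1); c <- sample.int(grid$px_cols, 1)
    if (is.na(layers[[k]][r, c])) {
      layers[[k]][r, c] <- sample.int(date_range, 1) + (k - 1L) * 400L
    }
  }
  structure(list(grid = grid, layers = layers), class = "pd_burn")
}

# O(n^2) union-find oracle over all observation pairs: two observations are
# linked when pixels are identical or adjacent and dates differ by <= gap
oracle_partition <- function(obs, connectivity, gap) {
  n <- nrow(obs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j >= i) break
      dr <- abs(obs$row[i] - obs$row[j]); dc <- abs(obs$col[i] - obs$col[j])
      adj <- if (connectivity == 8) dr <= 1 && dc <= 1 else
        (dr + dc <= 1)
      if (adj && abs(obs$date[i] - obs$date[j]) <= gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, 0L)
}

# canonical form of a partition labelling, for comparing partitions
canonical_partition <- function(labels) {
  match(labels, unique(labels))
}

# burn history holding exactly one fire with the given pixels/dates
single_fire_burn <- function(rows, cols, dates, n = 5, ppc = 4) {
  grid <- pd_grid(n, n, pixels_per_cell = ppc)
  layer <- matrix(NA_integer_, grid$px_rows, grid$px_cols)
  layer[cbind(rows, cols)] <- as.integer(dates)
  structure(list(grid = grid, layers = list(layer)), class = "pd_burn")
}

# balanced inside/outside data with a known PA contrast, for mixed-model tests
balanced_pa_data <- function(n_pa = 20, per_side = 5, beta = -0.3,
                             sd_pa = 0.5, sd_e = 1, seed = 1) {
  set.seed(seed)
  pa_id <- rep(sprintf("pa%02d", seq_len(n_pa)), each = 2 * per_side)
  status <- rep(rep(c("inside", "outside"), each = per_side), n_pa)
  b <- rep(rnorm(n_pa, 0, sd_pa), each = 2 * per_side)
  y <- 10 + beta * (status == "inside") + b + rnorm(length(b), 0, sd_e)
  tibble::tibble(y = y, status = status, pa_id = pa_id)
}

# Monte-Carlo membership estimate of a hull volume within the unit box
mc_hull_volume <- function(points, n_draws = 2e5, seed = 1, chunk = 1e5) {
  hs <- hull_halfspaces(points)
  d <- ncol(points)
  set.seed(seed)
  hits <- 0
  left <- n_draws
  while (left > 0) {
    m <- min(chunk, left)
    u <- matrix(runif(m * d), m, d)
    inside <- rowSums(u %*% t(hs$normals) >
                        matrix(hs$offsets, m, length(hs$offsets),
                               byrow = TRUE) + 1e-9) == 0
    hits <- hits + sum(inside)
    left <- left - m
  }
  hits / n_draws
}
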