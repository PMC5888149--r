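test_that("connectivity controls diagonal merging", {
  # two diagonal pixels burning the same day
  b <- single_fire_burn(rows = c(1, 2), cols = c(1, 2), dates = c(100, 100))
  expect_equal(nrow(delineate_fires(b, connectivity = 8)), 1)
  expect_equal(nrow(delineate_fires(b, connectivity = 4)), 2)
})

test_that("the date gap is an inclusive boundary", {
  b <- single_fire_burn(rows = c(1, 1), cols = c(1, 2), dates = c(100, 110))
  expect_equal(nrow(delineate_fires(b, date_gap_days = 8)), 2)
  expect_equal(nrow(delineate_fires(b, date_gap_days = 10)), 1)
})

test_that("chained links allow fires longer than the gap", {
  # dates 0, 8, 16: each link within the 8-day gap, total span 16
  b <- single_fire_burn(rows = c(1, 1, 1), cols = 1:3, dates = c(0, 8, 16))
  expect_equal(nrow(delineate_fires(b, date_gap_days = 8)), 1)
})

test_that("empty rasters give an empty fire table, not an error", {
  g <- pd_grid(5, 5, pixels_per_cell = 2)
  b <- structure(list(grid = g, layers = list(
    matrix(NA_integer_, g$px_rows, g$px_cols))), class = "pd_burn")
  expect_equal(nrow(delineate_fires(b)), 0)
})

test_that("flood fill matches a brute-force union-find oracle", {
  for (s in 1:12) {
    b <- random_burn(n_obs = 35, seed = s)
    obs <- pyrodiv:::burn_observations(b)
    for (conn in c(4, 8)) {
      for (gap in c(0, 8)) {
        fires <- delineate_fires(b, connectivity = conn, date_gap_days = gap)
        # implementation labels per observation, matched by pixel+date
        got <- rep(NA_integer_, nrow(obs))
        for (f in seq_len(nrow(fires))) {
          key <- paste(fires$px_row[[f]], fires$px_col[[f]], fires$px_date[[f]])
          got[match(key, paste(obs$row, obs$col, obs$date))] <- f
        }
        want <- oracle_partition(obs, conn, gap)
        expect_identical(canonical_partition(got), canonical_partition(want))
        # partition property: observations conserved
        expect_identical(sum(fires$n_pixels), nrow(obs))
      }
    }
  }
})

test_that("the fire partition ignores observation scan order", {
  b <- random_burn(n_obs = 40, seed = 99)
  obs <- pyrodiv:::burn_observations(b)
  lab1 <- floodfill_cpp(obs$row, obs$col, obs$date, b$grid$px_rows,
                        b$grid$px_cols, 8L, 8L)
  set.seed(1)
  perm <- sample.int(nrow(obs))
  lab2 <- floodfill_cpp(obs$row[perm], obs$col[perm], obs$date[perm],
                        b$grid$px_rows, b$grid$px_cols, 8L, 8L)
  expect_identical(canonical_partition(lab1),
                   canonical_partition(lab2[order(perm)]))
})

test_that("fireday handles the calendar wrap with a positive-after-peak sign", {
  jan15_2001 <- pd_date2day(as.Date("2001-01-15"))
  expect_identical(compute_fireday(jan15_2001, 1), 0L)
  feb14_2001 <- pd_date2day(as.Date("2001-02-14"))
  expect_identical(compute_fireday(feb14_2001, 1), 30L)
  dec16_2001 <- pd_date2day(as.Date("2001-12-16"))  # nearer next year's peak
  expect_identical(compute_fireday(dec16_2001, 1), -30L)
  # stays within the minimal circular range for arbitrary inputs
  set.seed(4)
  fd <- compute_fireday(sample.int(5000, 300), sample.int(12, 300, TRUE))
  expect_true(all(fd >= -182 & fd <= 183))
})

test_that("fire return interval matches the worked example and an oracle", {
  # 2-pixel fire with prior burns 365 and 730 days earlier
  g <- pd_grid(5, 5, pixels_per_cell = 2)
  l1 <- matrix(NA_integer_, 10, 10); l2 <- l1
  l1[1, 1] <- 1000L - 365L; l1[1, 2] <- 1000L - 730L
  l2[1, 1] <- 1000L; l2[1, 2] <- 1000L
  b <- structure(list(grid = g, layers = list(l1, l2)), class = "pd_burn")
  fires <- delineate_fires(b)
  f <- fires[fires$ignition_date == 1000, ]
  expect_equal(compute_fri(f, b), log(547.5), tolerance = 1e-12)
  # no earlier burn -> undefined, as a value
  f0 <- fires[fires$ignition_date < 1000, ][1, ]
  expect_true(is.na(compute_fri(f0, b)))

  # random histories: brute-force per-pixel scan
  for (s in 1:5) {
    b <- random_burn(n_obs = 40, n_layers = 4, seed = 200 + s)
    fires <- delineate_fires(b)
    for (i in seq_len(nrow(fires))) {
      f <- fires[i, ]
      since <- c()
      for (k in seq_along(f$px_row[[1]])) {
        r <- f$px_row[[1]][k]; c <- f$px_col[[1]][k]; d <- f$px_date[[1]][k]
        prior <- unlist(lapply(b$layers, function(l) l[r, c]))
        prior <- prior[!is.na(prior) & prior < d]
        if (length(prior) > 0) since <- c(since, d - max(prior))
      }
      want <- if (length(since) == 0) NA_real_ else log(mean(since))
      expect_equal(compute_fri(f, b), want)
    }
  }
})

test_that("FRP joining averages matched detections and flags the rest", {
  b <- single_fire_burn(rows = c(3, 3, 4), cols = c(3, 4, 3),
                        dates = c(50, 51, 52), n = 5, ppc = 4)
  g <- b$grid
  fires <- delineate_fires(b)
  det <- tibble::tibble(
    lon = pyrodiv:::pixel_lon(g, c(3, 4, 15)),
    lat = pyrodiv:::pixel_lat(g, c(3, 3, 15)),
    date = c(50L, 51L, 50L),
    frp_mw = c(10, 30, 99))
  out <- attach_frp(fires, det, g)
  expect_equal(out$logfrp, log(20))  # detection outside the footprint dropped
  expect_false(out$frp_excluded)

  # no detections at all -> flagged excluded
  out0 <- attach_frp(fires, det[0, ], g)
  expect_true(out0$frp_excluded)
  expect_true(is.na(out0$logfrp))
})

test_that("a padded detection near two fires goes to the nearest date", {
  # same pixel burns in two fires 40 days apart (different layers)
  g <- pd_grid(5, 5, pixels_per_cell = 2)
  l1 <- matrix(NA_integer_, 10, 10); l2 <- l1
  l1[2, 2] <- 100L; l2[2, 2] <- 140L
  b <- structure(list(grid = g, layers = list(l1, l2)), class = "pd_burn")
  fires <- delineate_fires(b, date_gap_days = 8)
  expect_equal(nrow(fires), 2)
  det <- tibble::tibble(lon = pyrodiv:::pixel_lon(g, 2),
                        lat = pyrodiv:::pixel_lat(g, 2),
                        date = 139L, frp_mw = 5)
  out <- attach_frp(fires, det, g, temporal_pad_days = 60)
  expect_true(is.na(out$logfrp[out$ignition_date == 100]))
  expect_equal(out$logfrp[out$ignition_date == 140], log(5))
})

test_that("FRP matching agrees with a brute-force all-pairs oracle", {
  set.seed(31)
  b <- random_burn(n_obs = 45, seed = 31)
  g <- b$grid
  fires <- delineate_fires(b)
  n_det <- 30
  det <- tibble::tibble(
    lon = runif(n_det, g$origin_lon, g$origin_lon + g$n_cols * g$cell_deg),
    lat = runif(n_det, g$origin_lat - g$n_rows * g$cell_deg, g$origin_lat),
    date = sample.int(80, n_det, replace = TRUE),
    frp_mw = runif(n_det, 1, 50))
  pad <- 2
  out <- attach_frp(fires, det, g, temporal_pad_days = pad)
  # oracle: point-in-footprint by pixel identity, then date window + nearest
  px <- pyrodiv:::pixel_of_lonlat(g, det$lon, det$lat)
  assign_to <- rep(NA_integer_, n_det)
  for (i in seq_len(n_det)) {
    best <- NA_integer_; best_d <- Inf
    for (f in seq_len(nrow(fires))) {
      inside <- any(fires$px_row[[f]] == px$prow[i] &
                      fires$px_col[[f]] == px$pcol[i])
      if (!inside) next
      if (det$date[i] < fires$ignition_date[f] - pad ||
          det$date[i] > fires$last_date[f] + pad) next
      dd <- max(0, fires$ignition_date[f] - det$date[i],
                det$date[i] - fires$last_date[f])
      if (dd < best_d || (dd == best_d && fires$fire_id[f] < best)) {
        best <- fires$fire_id[f]; best_d <- dd
      }
    }
    assign_to[i] <- best
  }
  want <- tapply(det$frp_mw, assign_to, mean)
  for (f in seq_len(nrow(fires))) {
    id <- as.character(fires$fire_id[f])
    if (id %in% names(want)) {
      expect_equal(out$logfrp[f], log(unname(want[id])))
    } else {
      expect_true(out$frp_excluded[f])
    }
  }
})

test_that("the assembled fire table filters on both FRI and FRP", {
  env <- test_env(10)
  fh <- gen_fire_history(env, years = 4, seed = 3)
  fires <- delineate_fires(fh$burn)
  fires <- attach_frp(fires, fh$detections, env$grid)
  ft <- assemble_fire_table(fires, fh$burn, env$cells)
  excl <- attr(ft, "exclusions")
  expect_named(excl, c("no_fri", "no_frp", "off_grid"))
  expect_true(all(!is.na(ft$logfri)) && all(!is.na(ft$logfrp)))
  expect_true(all(ft$fireday >= -182 & ft$fireday <= 183))
  expect_true(all(ft$logarea == log(ft$n_pixels * env$grid$pixel_area_km2)))
  # retained + excluded-by-some-rule covers all delineated fires
  expect_gte(nrow(fires) - nrow(ft), max(excl))

  # CSV round trip
  f <- tempfile(fileext = ".csv")
  readr::write_csv(ft, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(ft), tolerance = 1e-12,
               ignore_attr = TRUE)
})
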