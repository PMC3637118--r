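test_that("density surface matches the closed form and conserves mass", {
  # cell size 8 puts a cell center exactly on the fix (offset h + c from the
  # grid origin is a whole number of cells)
  p <- kd_params(100, cell_size = 8)
  tr <- stationary_track(1, x = 500, y = 500)
  surf <- compute_density_surface(tr, p)
  # at the fix itself the quartic kernel evaluates to 3 / (pi h^2)
  expect_equal(max(surf$values), 3 / (pi * 100^2), tolerance = 1e-9)

  # zero outside the kernel support
  cx <- surf$origin[["x0"]] + (seq_len(surf$n_cols) - 0.5) * surf$cell_size
  cy <- surf$origin[["y0"]] + (seq_len(surf$n_rows) - 0.5) * surf$cell_size
  far <- outer((cy - 500)^2, (cx - 500)^2, "+") > 100^2
  expect_true(all(surf$values[far] == 0))

  # mass conservation: sum * cell area ~ number of fixes, within 1%
  set.seed(42)
  tr2 <- tibble::tibble(track_id = "m", t = seq(0, 990, 10),
                        x = rnorm(100, 0, 150), y = rnorm(100, 0, 150))
  for (h in c(50, 200, 1000)) {
    s <- compute_density_surface(tr2, kd_params(h))
    mass <- sum(s$values) * s$cell_size^2
    expect_equal(mass, 100, tolerance = 0.01)
  }

  expect_error(compute_density_surface(tr2[0, ], p), "no fixes")
})

test_that("optimized surface equals brute-force summation", {
  set.seed(11)
  tr <- tibble::tibble(track_id = "b", t = seq(0, 40) * 10,
                       x = runif(41, 0, 400), y = runif(41, 0, 400))
  for (h in c(30, 120)) {
    p <- kd_params(h)
    surf <- compute_density_surface(tr, p)
    oracle <- brute_force_surface(tr, surf)
    expect_equal(max(abs(surf$values - oracle)) / max(oracle), 0,
                 tolerance = 1e-9)
  }
})

test_that("peak extraction finds the right maxima", {
  p <- kd_params(100)
  # one cluster -> one peak at its location
  surf <- compute_density_surface(stationary_track(30, 200, 300), p)
  pk <- extract_peaks(surf)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$x - 200), p$cell_size)
  expect_lt(abs(pk$y - 300), p$cell_size)

  # two clusters 4h apart -> two peaks, ordered by descending density
  tr2 <- dplyr::bind_rows(stationary_track(50, 0, 0),
                          stationary_track(30, 400, 0, t0 = 1000))
  pk2 <- extract_peaks(compute_density_surface(tr2, p))
  expect_equal(nrow(pk2), 2)
  expect_true(pk2$density[1] > pk2$density[2])
  expect_lt(abs(pk2$x[1] - 0), p$cell_size)
  expect_lt(abs(pk2$x[2] - 400), p$cell_size)

  # all-zero surface -> no peaks
  empty <- structure(list(origin = c(x0 = 0, y0 = 0), cell_size = 10,
                          n_rows = 5L, n_cols = 5L, bandwidth = 100,
                          values = matrix(0, 5, 5)),
                     class = "density_surface")
  expect_equal(nrow(extract_peaks(empty)), 0)

  # non-maximum suppression drops the weaker of two near peaks
  pk3 <- extract_peaks(compute_density_surface(tr2, p), suppress_radius = 500)
  expect_equal(nrow(pk3), 1)
  expect_lt(abs(pk3$x - 0), p$cell_size)
})

test_that("peak count is non-increasing in bandwidth on a fixed fixture", {
  set.seed(3)
  centers <- cbind(runif(5, 0, 3000), runif(5, 0, 3000))
  tr <- dplyr::bind_rows(lapply(seq_len(5), function(k) {
    stationary_track(40, centers[k, 1], centers[k, 2], t0 = (k - 1) * 1000)
  }))
  counts <- vapply(c(50, 100, 200, 500, 1000), function(h) {
    nrow(extract_peaks(compute_density_surface(tr, kd_params(h))))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fix allocation uses nearest peak with bandwidth cutoff and ties", {
  peaks <- tibble::tibble(peak_id = 1:2, x = c(0, 100), y = 0,
                          density = c(2, 1))
  p <- kd_params(50)
  tr <- tibble::tibble(track_id = "a", t = c(0, 10, 20, 30),
                       x = c(0, 100, 50, 300), y = 0)
  lab <- assign_fixes(tr, peaks, p)
  expect_equal(lab[1], 1L)          # exactly at peak 1
  expect_equal(lab[2], 2L)          # exactly at peak 2
  expect_equal(lab[3], 1L)          # equidistant tie -> lowest peak id
  expect_true(is.na(lab[4]))        # farther than h from every peak
})

test_that("visit construction merges runs across short gaps", {
  p <- kd_params(100, merge_gap = 60)
  # 31 consecutive fixes labeled A at 10 s -> one visit of 300 s
  v <- build_visits(rep(1L, 31), seq(0, 300, 10), p)
  expect_equal(nrow(v), 1)
  expect_equal(v$t_end - v$t_start, 300)
  expect_equal(v$n_fixes, 31L)

  # a 290 s run still becomes a visit (filtering happens later)
  v2 <- build_visits(rep(2L, 30), seq(0, 290, 10), p)
  expect_equal(v2$t_end - v2$t_start, 290)

  # A-run, one trip fix, A-run -> a single merged visit spanning the gap
  lab <- c(rep(1L, 10), NA, rep(1L, 10))
  v3 <- build_visits(lab, seq(0, 200, 10), p)
  expect_equal(nrow(v3), 1)
  expect_equal(v3$t_end - v3$t_start, 200)
  expect_equal(v3$n_fixes, 20L)

  # a gap wider than merge_gap keeps visits apart
  lab4 <- c(rep(1L, 10), rep(NA, 8), rep(1L, 10))
  v4 <- build_visits(lab4, seq(0, 270, 10), p)
  expect_equal(nrow(v4), 2)
})

test_that("noiseless synthetic stops are recovered at every bandwidth", {
  set.seed(5)
  # three stops pairwise far apart relative to the largest tested bandwidth
  p <- dwell_track(rbind(c(0, 0), c(2600, 2500), c(5200, 0)),
                   c(600, 2000, 900))
  for (h in c(10, 50, 100, 200, 500)) {
    prm <- kd_params(h)
    stops <- detect_stops_kd(p$track, prm)
    expect_equal(nrow(stops), 3)
    m <- match_stops(stops, p$truth)
    expect_true(all(m$distance <= prm$cell_size))
    # trip fixes within h of a peak join its visits, so the duration carries
    # a structural overestimate of up to 2 h / speed on top of sampling
    true_dur <- p$truth$t_depart - p$truth$t_arrive
    err <- stops$total_duration_s - true_dur[m$true_stop_id]
    expect_true(all(err >= -20 & err <= 20 + 2 * h / 10))
    expect_stops_schema(stops)
    # detected stops come back in chronological order
    expect_true(!is.unsorted(stops$t_first))
  }
})

test_that("every detected stop satisfies the duration and support floors", {
  set.seed(21)
  cfg <- generator_config(n_tracks = 6, master_seed = 21)
  ts <- generate_track_set(cfg)
  for (id in unique(ts$tracks$track_id)) {
    tr <- ts$tracks[ts$tracks$track_id == id, ]
    for (h in c(50, 200)) {
      prm <- kd_params(h)
      stops <- detect_stops_kd(tr, prm)
      if (nrow(stops) == 0) next
      expect_true(all(stops$total_duration_s >= prm$min_stop_duration))
      expect_true(all(stops$n_fixes >= prm$min_peak_support))
      expect_lte(sum(stops$n_fixes), nrow(tr))
    }
  }
})

test_that("detection is equivariant under whole-cell translation", {
  set.seed(8)
  cfg <- generator_config(n_tracks = 1, master_seed = 8)
  plan <- sample_stop_plan(cfg, seed = 4)
  path <- build_noiseless_path(plan, cfg)
  set.seed(99)
  tr <- apply_noise(path$track, 80)
  prm <- kd_params(200)
  shift <- 7 * prm$cell_size
  tr2 <- tr
  tr2$x <- tr2$x + shift
  tr2$y <- tr2$y - shift
  a <- detect_stops_kd(tr, prm)
  b <- detect_stops_kd(tr2, prm)
  expect_equal(nrow(a), nrow(b))
  expect_equal(b$x - a$x, rep(shift, nrow(a)), tolerance = 1e-9)
  expect_equal(b$y - a$y, rep(-shift, nrow(a)), tolerance = 1e-9)
  expect_equal(a$total_duration_s, b$total_duration_s)
})
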