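# Small in-code fixtures shared across the suite.

# A track dwelling at given centers for given durations, travelling straight
# between them at `speed`, sampled every `dt` seconds (noise-free).
dwell_track <- function(centers, durations, speed = 10, dt = 10,
                        id = "trk") {
  plan <- list(stops = tibble::tibble(
    stop_id = seq_len(nrow(centers)),
    cx = centers[, 1], cy = centers[, 2],
    duration_s = durations, category = 1L
  ), noise_m = 0, seed = NA_integer_)
  cfg <- generator_config(n_tracks = 1, n_stops = nrow(centers),
                          speed = speed, fix_interval = dt)
  build_noiseless_path(plan, cfg, track_id = id)
}

# n coincident fixes at (x, y), dt seconds apart, then optional movement away.
stationary_track <- function(n, x = 0, y = 0, dt = 10, t0 = 0, id = "trk") {
  tibble::tibble(track_id = id, t = t0 + dt * (seq_len(n) - 1), x = x, y = y)
}

# Brute-force quartic KDE evaluated at every cell center; the independent
# oracle for the kernel-stamping implementation.
brute_force_surface <- function(track, surface) {
  h <- surface$bandwidth
  vals <- matrix(0, surface$n_rows, surface$n_cols)
  for (i in seq_len(surface$n_rows)) {
    cy <- surface$origin[["y0"]] + (i - 0.5) * surface$cell_size
    for (j in seq_len(surface$n_cols)) {
      cx <- surface$origin[["x0"]] + (j - 0.5) * surface$cell_size
      d2 <- (track$x - cx)^2 + (track$y - cy)^2
      u <- 1 - d2 / h^2
      vals[i, j] <- sum(3 / (pi * h^2) * u[d2 <= h^2]^2)
    }
  }
  vals
}

expect_stops_schema <- function(stops) {
  expect_true(all(c("stop_id", "x", "y", "t_first", "t_last",
                    "total_duration_s", "n_visits", "n_fixes", "visits")
                  %in% names(stops)))
}
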