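#' Configuration for the synthetic track generator
#'
#' Describes the simulated study design: a batch of tracks, each visiting
#' `n_stops` places placed uniformly in a square area, dwelling at each for a
#' duration drawn from one of three categories, and travelling between them in
#' a straight line at constant speed. Every fix is displaced by isotropic
#' Gaussian noise whose per-axis standard deviation is drawn once per track,
#' uniformly on `[0, noise_max]`.
#'
#' @param n_tracks Number of tracks (default 750).
#' @param n_stops Stops per track (default 3).
#' @param area_side Side of the square placement area, meters (default 6000).
#' @param speed Travel speed on trip legs, m/s (default 10, i.e. 36 km/h).
#' @param fix_interval Time between consecutive fixes, seconds (default 10).
#' @param master_seed Integer master seed; per-track substreams are derived
#'   from it so each track is individually reproducible.
#' @param duration_bounds List of three `(lo, hi)` pairs in minutes, one per
#'   stop-duration category (defaults `(6,20)`, `(20,120)`, `(120,360)`).
#'   Lower bounds must be at least 5 minutes so every simulated stop is long
#'   enough to qualify for detection.
#' @param noise_max Upper bound of the per-track noise SD, meters (default
#'   200).
#' @param noise_stops_only If `TRUE`, only fixes inside stop dwell windows are
#'   displaced; trip fixes stay exact. Default `FALSE` (noise everywhere).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_tracks = 750, n_stops = 3, area_side = 6000,
                             speed = 10, fix_interval = 10, master_seed = 1,
                             duration_bounds = list(c(6, 20), c(20, 120),
                                                    c(120, 360)),
                             noise_max = 200, noise_stops_only = FALSE) {
  stopifnot(n_tracks >= 1, n_stops >= 1, area_side > 0, speed > 0,
            fix_interval > 0, noise_max >= 0,
            length(duration_bounds) == 3)
  for (b in duration_bounds) {
    stopifnot(length(b) == 2, b[1] > 0, b[2] > b[1])
    if (b[1] * 60 < 300) {
      stop("duration category lower bound below the 5-minute minimal stop")
    }
  }
  structure(list(n_tracks = as.integer(n_tracks),
                 n_stops = as.integer(n_stops),
                 area_side = area_side, speed = speed,
                 fix_interval = fix_interval,
                 master_seed = as.integer(master_seed),
                 duration_bounds = duration_bounds,
                 noise_max = noise_max,
                 noise_stops_only = isTRUE(noise_stops_only)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic track generator configuration\n")
  cat(sprintf("  %d tracks x %d stops, %g m square, %g m/s, fix every %g s\n",
              x$n_tracks, x$n_stops, x$area_side, x$speed, x$fix_interval))
  cat(sprintf("  noise SD ~ U[0, %g] m (%s); master seed %d\n", x$noise_max,
              if (x$noise_stops_only) "stops only" else "all fixes",
              x$master_seed))
  invisible(x)
}

#' Draw a stop plan for one track
#'
#' Samples `n_stops` centers uniformly in the area square (visiting order =
#' draw order), a duration category uniformly among the three categories per
#' stop with the duration uniform within the category's bounds, and the
#' per-track noise SD uniform on `[0, noise_max]`. Arrival and departure
#' times are filled in later by [build_noiseless_path()].
#'
#' @param config A [generator_config()].
#' @param seed Optional integer; when given the plan is drawn from a local
#'   stream seeded with it, making the plan a pure function of
#'   `(config, seed)`.
#' @return A list with elements `stops` (tibble `stop_id, cx, cy, duration_s,
#'   category`), `noise_m`, and `seed`.
#' @export
sample_stop_plan <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_stops
  cx <- runif(n, 0, config$area_side)
  cy <- runif(n, 0, config$area_side)
  cat_idx <- sample.int(3, n, replace = TRUE)
  dur <- vapply(cat_idx, function(k) {
    b <- config$duration_bounds[[k]]
    runif(1, b[1] * 60, b[2] * 60)
  }, numeric(1))
  noise_m <- runif(1, 0, config$noise_max)
  list(stops = tibble::tibble(stop_id = seq_len(n), cx = cx, cy = cy,
                              duration_s = dur, category = cat_idx),
       noise_m = noise_m,
       seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Trace the exact (noise-free) trajectory of a stop plan
#'
#' The track starts at the first stop center at t = 0, dwells there for the
#' stop's duration, then travels in a straight line at constant speed to the
#' next stop, and so on. Fixes are sampled every `fix_interval` seconds along
#' this piecewise-linear schedule. Realized arrival/departure times are
#' returned as the track's ground truth.
#'
#' @param plan A stop plan from [sample_stop_plan()].
#' @param config The [generator_config()].
#' @param track_id Identifier for the generated track.
#' @return A list with `track` (tibble `track_id, t, x, y`) and `truth`
#'   (tibble `track_id, stop_id, cx, cy, t_arrive, t_depart, noise_m`).
#' @export
build_noiseless_path <- function(plan, config, track_id = "track_001") {
  st <- plan$stops
  n <- nrow(st)
  t_arrive <- numeric(n)
  t_depart <- numeric(n)
  t_arrive[1] <- 0
  t_depart[1] <- st$duration_s[1]
  if (n > 1) {
    for (k in 2:n) {
      leg <- sqrt((st$cx[k] - st$cx[k - 1])^2 + (st$cy[k] - st$cy[k - 1])^2)
      t_arrive[k] <- t_depart[k - 1] + leg / config$speed
      t_depart[k] <- t_arrive[k] + st$duration_s[k]
    }
  }
  # piecewise-linear knots: position is constant on [arrive, depart] and
  # linear between a departure and the next arrival
  knot_t <- as.vector(rbind(t_arrive, t_depart))
  knot_x <- rep(st$cx, each = 2)
  knot_y <- rep(st$cy, each = 2)
  tt <- seq(0, t_depart[n], by = config$fix_interval)
  track <- tibble::tibble(
    track_id = track_id, t = tt,
    x = approx(knot_t, knot_x, xout = tt, ties = "ordered")$y,
    y = approx(knot_t, knot_y, xout = tt, ties = "ordered")$y
  )
  truth <- tibble::tibble(track_id = track_id, stop_id = st$stop_id,
                          cx = st$cx, cy = st$cy,
                          t_arrive = t_arrive, t_depart = t_depart,
                          noise_m = plan$noise_m)
  list(track = track, truth = truth)
}

#' Displace fixes by Gaussian positional noise
#'
#' Adds independent zero-mean Gaussian offsets with per-axis standard
#' deviation `noise_m` to each fix (isotropic bivariate noise); timestamps are
#' untouched. When `windows` is supplied, only fixes whose times fall inside
#' one of the `[t_arrive, t_depart]` windows are displaced.
#'
#' @param track Planar track table.
#' @param noise_m Per-axis standard deviation, meters (>= 0).
#' @param windows Optional data frame with `t_arrive`, `t_depart` columns.
#' @return The displaced track table.
#' @export
apply_noise <- function(track, noise_m, windows = NULL) {
  if (noise_m < 0) stop("noise_m must be >= 0")
  if (noise_m == 0) return(track)
  sel <- rep(TRUE, nrow(track))
  if (!is.null(windows)) {
    sel <- rep(FALSE, nrow(track))
    for (k in seq_len(nrow(windows))) {
      sel <- sel | (track$t >= windows$t_arrive[k] &
                      track$t <= windows$t_depart[k])
    }
  }
  n <- sum(sel)
  track$x[sel] <- track$x[sel] + rnorm(n, 0, noise_m)
  track$y[sel] <- track$y[sel] + rnorm(n, 0, noise_m)
  track
}

#' Generate a full synthetic track set with ground truth
#'
#' Draws one stop plan per track, traces its noise-free path and applies the
#' track's Gaussian noise. Each track uses its own RNG substream derived from
#' the master seed, so the set is reproducible as a whole and per track.
#'
#' @param config A [generator_config()].
#' @return A list with `tracks` (all fixes, `track_id, t, x, y`) and `truth`
#'   (all true stops with realized times and per-track `noise_m`).
#' @export
generate_track_set <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$master_seed)
  track_seeds <- sample.int(.Machine$integer.max - 1L, config$n_tracks)
  ids <- sprintf("track_%04d", seq_len(config$n_tracks))
  tracks <- vector("list", config$n_tracks)
  truths <- vector("list", config$n_tracks)
  for (i in seq_len(config$n_tracks)) {
    set.seed(track_seeds[i])
    plan <- sample_stop_plan(config)
    path <- build_noiseless_path(plan, config, track_id = ids[i])
    win <- if (config$noise_stops_only) path$truth else NULL
    tracks[[i]] <- apply_noise(path$track, plan$noise_m, windows = win)
    truths[[i]] <- path$truth
  }
  list(tracks = dplyr::bind_rows(tracks), truth = dplyr::bind_rows(truths))
}
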