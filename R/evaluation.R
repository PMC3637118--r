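#' Classify a processed track against its ground truth
#'
#' A track is `on_target` when exactly as many stops as the truth holds were
#' detected and every detected stop lies within `outlier_dist` of some true
#' stop; `false_negative` / `false_positive` when fewer / more stops were
#' detected; and `outlier_discarded` when the count matches but a detected
#' stop is farther than `outlier_dist` from every true stop (a coincidental
#' count arising from compensating errors).
#'
#' @param detected Detected-stop table for one track (needs `x`, `y`).
#' @param truth Truth table for the same track (needs `cx`, `cy`).
#' @param outlier_dist Outlier distance threshold, meters (default 1000).
#' @return One of `"on_target"`, `"false_negative"`, `"false_positive"`,
#'   `"outlier_discarded"`.
#' @export
classify_track <- function(detected, truth, outlier_dist = 1000) {
  n_true <- nrow(truth)
  n_det <- nrow(detected)
  if (n_det < n_true) return("false_negative")
  if (n_det > n_true) return("false_positive")
  d <- nearest_true_distance(detected, truth)
  if (any(d > outlier_dist)) return("outlier_discarded")
  "on_target"
}

nearest_true_distance <- function(detected, truth) {
  vapply(seq_len(nrow(detected)), function(i) {
    min(sqrt((detected$x[i] - truth$cx)^2 + (detected$y[i] - truth$cy)^2))
  }, numeric(1))
}

#' Match detected stops to their closest true stops
#'
#' Each detected stop is matched to the nearest true stop (by Euclidean
#' distance); the relative duration error is `(found - true) / true` using
#' the detected stop's total visit duration against the matched true stop's
#' dwell time. By default matching is independent per detected stop; with
#' `one_to_one = TRUE` a minimal-total-distance one-to-one assignment is used
#' instead (exhaustive over permutations, so only for small stop counts).
#'
#' @param detected Detected-stop table for one track (`x`, `y`,
#'   `total_duration_s`).
#' @param truth Truth table for the same track (`cx`, `cy`, `t_arrive`,
#'   `t_depart`, `stop_id`).
#' @param one_to_one Use a one-to-one assignment (default `FALSE`).
#' @return A tibble `stop_id, true_stop_id, distance, duration_error`; empty
#'   when no stops were detected.
#' @export
match_stops <- function(detected, truth, one_to_one = FALSE) {
  if (nrow(detected) == 0) {
    return(tibble::tibble(stop_id = integer(), true_stop_id = integer(),
                          distance = numeric(), duration_error = numeric()))
  }
  dmat <- outer(seq_len(nrow(detected)), seq_len(nrow(truth)),
                function(i, j) {
                  sqrt((detected$x[i] - truth$cx[j])^2 +
                         (detected$y[i] - truth$cy[j])^2)
                })
  if (one_to_one && nrow(detected) == nrow(truth)) {
    n <- nrow(truth)
    if (n > 7) stop("one-to-one matching supported for at most 7 stops")
    perms <- permutations_of(n)
    costs <- apply(perms, 1, function(p) sum(dmat[cbind(seq_len(n), p)]))
    j <- perms[which.min(costs), ]
  } else {
    j <- apply(dmat, 1, which.min)
  }
  true_dur <- truth$t_depart[j] - truth$t_arrive[j]
  tibble::tibble(
    stop_id = detected$stop_id,
    true_stop_id = truth$stop_id[j],
    distance = dmat[cbind(seq_len(nrow(detected)), j)],
    duration_error = (detected$total_duration_s - true_dur) / true_dur
  )
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

NOISE_BIN_LEVELS <- c("[0,50)", "[50,100)", "[100,150)", "[150,200]")
DURATION_BIN_LEVELS <- c("[0,20min)", "[20min,2h)", "[2h,Inf)")

#' Bin a noise magnitude or stop duration into the study's categories
#'
#' Noise bins are the four 50 m ranges `[0,50), [50,100), [100,150),
#' [150,200]` (half-open, last closed). Duration bins are `[0, 20 min)`,
#' `[20 min, 2 h)` and `[2 h, Inf)`.
#'
#' @param noise_m Per-track noise SD, meters, in `[0, 200]`.
#' @return A factor with the bin labels.
#' @export
noise_bin <- function(noise_m) {
  if (any(noise_m < 0 | noise_m > 200)) {
    stop("noise_m out of range [0, 200]")
  }
  idx <- pmin(floor(noise_m / 50), 3) + 1
  factor(NOISE_BIN_LEVELS[idx], levels = NOISE_BIN_LEVELS)
}

#' @rdname noise_bin
#' @param duration_s Stop duration, seconds (>= 0).
#' @export
duration_bin <- function(duration_s) {
  if (any(duration_s < 0)) stop("negative duration")
  idx <- ifelse(duration_s < 20 * 60, 1L,
                ifelse(duration_s < 120 * 60, 2L, 3L))
  factor(DURATION_BIN_LEVELS[idx], levels = DURATION_BIN_LEVELS)
}

#' Close-stop discrimination counts
#'
#' Restricts to tracks whose ground truth contains two or more stops within
#' `radius` of each other and counts, per algorithm and bandwidth, how many
#' of those tracks were classified on target — the ability to resolve
#' close-by places despite smoothing.
#'
#' @param results Tidy result table (`track_id, algo, bandwidth_m,
#'   classification`), one row per track x algorithm x bandwidth.
#' @param truth Full truth table.
#' @param radius Neighbour radius, meters (default 800).
#' @return A tibble `algo, bandwidth_m, n_close_tracks, n_on_target`.
#' @export
close_stop_discrimination <- function(results, truth, radius = 800) {
  close_ids <- Filter(function(id) {
    st <- truth[truth$track_id == id, ]
    if (nrow(st) < 2) return(FALSE)
    d <- as.matrix(stats::dist(cbind(st$cx, st$cy)))
    any(d[upper.tri(d)] <= radius)
  }, unique(truth$track_id))
  sub <- results[results$track_id %in% close_ids, ]
  out <- dplyr::summarise(
    dplyr::group_by(sub, .data$algo, .data$bandwidth_m),
    n_close_tracks = dplyr::n(),
    n_on_target = sum(.data$classification == "on_target"),
    .groups = "drop"
  )
  attr(out, "close_track_ids") <- close_ids
  out
}

#' Sensitivity of detection to the bandwidth choice
#'
#' For each track (evaluated at every bandwidth), records the smallest and
#' largest bandwidth with an on-target classification; tracks never on target
#' are excluded. Averages are reported per algorithm and noise bin — a wider
#' min-to-max range means the algorithm tolerates a broader range of
#' bandwidth values.
#'
#' @param results Tidy result table with a `noise_m` column.
#' @return A tibble `algo, noise_bin, n_tracks, mean_min_bw, mean_max_bw`.
#' @export
bandwidth_sensitivity <- function(results) {
  ok <- results[results$classification == "on_target", ]
  per_track <- dplyr::summarise(
    dplyr::group_by(ok, .data$algo, .data$track_id),
    min_bw = min(.data$bandwidth_m), max_bw = max(.data$bandwidth_m),
    noise_m = .data$noise_m[1], .groups = "drop"
  )
  per_track$noise_bin <- noise_bin(per_track$noise_m)
  dplyr::summarise(
    dplyr::group_by(per_track, .data$algo, .data$noise_bin),
    n_tracks = dplyr::n(),
    mean_min_bw = mean(.data$min_bw), mean_max_bw = mean(.data$max_bw),
    .groups = "drop"
  )
}

#' Aggregate per-stratum performance metrics
#'
#' Summarises the tidy result table into per-stratum rows: classification
#' percentages (which partition 100%), the mean detected stop count, and —
#' over on-target tracks only, where the detected-to-true correspondence is
#' meaningful — mean and SD of the match distance and of the signed and
#' absolute relative duration errors.
#'
#' @param results Tidy result table (`track_id, algo, bandwidth_m, noise_m,
#'   n_detected, classification`).
#' @param matches Per-stop match table for on-target tracks (`algo,
#'   bandwidth_m, track_id, distance, duration_error`).
#' @param by Extra stratification: `"none"` for algo x bandwidth only, or
#'   `"noise"` to add the noise bin (default).
#' @return A tibble, one row per stratum, with `n_tracks`, `pct_on_target`,
#'   `pct_false_neg`, `pct_false_pos`, `pct_outlier`, `mean_n_stops`,
#'   `mean_distance`, `sd_distance`, `mean_duration_error`,
#'   `sd_duration_error`, `mean_abs_duration_error` (percentage fields in
#'   0-100, duration errors in %).
#' @export
summarize_metrics <- function(results, matches, by = c("noise", "none")) {
  by <- match.arg(by)
  results$noise_bin <- noise_bin(results$noise_m)
  keys <- c("algo", "bandwidth_m", if (by == "noise") "noise_bin")
  cls <- dplyr::summarise(
    dplyr::group_by(results, dplyr::across(dplyr::all_of(keys))),
    n_tracks = dplyr::n(),
    pct_on_target = 100 * mean(.data$classification == "on_target"),
    pct_false_neg = 100 * mean(.data$classification == "false_negative"),
    pct_false_pos = 100 * mean(.data$classification == "false_positive"),
    pct_outlier = 100 * mean(.data$classification == "outlier_discarded"),
    mean_n_stops = mean(.data$n_detected),
    .groups = "drop"
  )
  if (nrow(matches) > 0) {
    mm <- dplyr::left_join(
      matches,
      results[, c("algo", "bandwidth_m", "track_id", "noise_bin")],
      by = c("algo", "bandwidth_m", "track_id")
    )
    acc <- dplyr::summarise(
      dplyr::group_by(mm, dplyr::across(dplyr::all_of(keys))),
      mean_distance = mean(.data$distance),
      sd_distance = sd(.data$distance),
      mean_duration_error = 100 * mean(.data$duration_error),
      sd_duration_error = 100 * sd(.data$duration_error),
      mean_abs_duration_error = 100 * mean(abs(.data$duration_error)),
      .groups = "drop"
    )
    cls <- dplyr::left_join(cls, acc, by = keys)
  } else {
    cls$mean_distance <- cls$sd_distance <- NA_real_
    cls$mean_duration_error <- cls$sd_duration_error <- NA_real_
    cls$mean_abs_duration_error <- NA_real_
  }
  cls
}
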