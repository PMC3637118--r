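#' Configuration of a full benchmark run
#'
#' @param generator A [generator_config()] describing the synthetic track set.
#' @param bandwidths Bandwidth values (meters) applied to both algorithms,
#'   strictly increasing (default `c(10, 50, 100, 200, 500, 1000)`).
#' @param algorithms Algorithms to run, a subset of `c("kd", "ft")`.
#' @param min_stop_duration Minimal stay duration, seconds (default 300).
#' @param output_dir Optional directory; when set, raw results and all
#'   summary tables are written there as CSV.
#' @param verbose Print per-stage progress (default `FALSE`).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(generator = generator_config(),
                              bandwidths = c(10, 50, 100, 200, 500, 1000),
                              algorithms = c("kd", "ft"),
                              min_stop_duration = 300,
                              output_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(generator, "generator_config"),
            all(bandwidths > 0), !is.unsorted(bandwidths, strictly = TRUE),
            all(algorithms %in% c("kd", "ft")), length(algorithms) >= 1,
            min_stop_duration > 0)
  structure(list(generator = generator, bandwidths = bandwidths,
                 algorithms = algorithms,
                 min_stop_duration = min_stop_duration,
                 output_dir = output_dir, verbose = isTRUE(verbose)),
            class = "experiment_config")
}

default_detectors <- function(config) {
  list(
    kd = function(track, bandwidth) {
      detect_stops_kd(track, kd_params(
        bandwidth, min_stop_duration = config$min_stop_duration))
    },
    ft = function(track, bandwidth) {
      detect_stops_ft(track, ft_params(
        bandwidth, min_stop_duration = config$min_stop_duration))
    }
  )[config$algorithms]
}

#' Run the full factorial benchmark
#'
#' Generates the synthetic track set once, runs every requested algorithm at
#' every bandwidth over every track, classifies each run against the ground
#' truth, and records per-stop matches for on-target tracks. With the
#' defaults this is 750 tracks x 6 bandwidths x 2 algorithms = 4,500
#' detection runs per algorithm.
#'
#' @param config An [experiment_config()].
#' @param detectors Optional named list of detector functions
#'   `function(track, bandwidth) -> stops` overriding the built-in
#'   algorithms (used e.g. to inject an oracle detector in validation).
#' @param track_set Optional pre-generated `list(tracks, truth)`; by default
#'   the set is generated from `config$generator`.
#' @return A list of class `experiment_result` with elements `truth`,
#'   `results` (one row per track x algo x bandwidth: `track_id, algo,
#'   bandwidth_m, noise_m, n_detected, classification`), `matches` (per-stop
#'   matches on on-target tracks), `stops` (all detected stops in the
#'   stops-CSV schema) and `config`.
#' @export
run_experiment <- function(config, detectors = NULL, track_set = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- Sys.time()
  if (is.null(track_set)) track_set <- generate_track_set(config$generator)
  if (is.null(detectors)) detectors <- default_detectors(config)
  if (config$verbose) {
    message(sprintf("generated %d tracks (%.1f s)",
                    length(unique(track_set$tracks$track_id)),
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  tracks_by_id <- split(track_set$tracks, track_set$tracks$track_id)
  truth_by_id <- split(track_set$truth, track_set$truth$track_id)
  ids <- names(tracks_by_id)
  res_rows <- list()
  match_rows <- list()
  stop_rows <- list()
  k <- 0L
  for (algo in names(detectors)) {
    ta <- Sys.time()
    for (bw in config$bandwidths) {
      for (id in ids) {
        track <- tracks_by_id[[id]]
        truth <- truth_by_id[[id]]
        stops <- detectors[[algo]](track, bw)
        cls <- classify_track(stops, truth)
        k <- k + 1L
        res_rows[[k]] <- tibble::tibble(
          track_id = id, algo = algo, bandwidth_m = bw,
          noise_m = truth$noise_m[1], n_detected = nrow(stops),
          classification = cls
        )
        if (cls == "on_target" && nrow(stops) > 0) {
          m <- match_stops(stops, truth)
          m$track_id <- id
          m$algo <- algo
          m$bandwidth_m <- bw
          match_rows[[length(match_rows) + 1L]] <- m
        }
        if (nrow(stops) > 0) {
          stop_rows[[length(stop_rows) + 1L]] <- tibble::tibble(
            algo = algo, bandwidth_m = bw, track_id = id,
            stop_id = stops$stop_id, x = stops$x, y = stops$y,
            total_duration_s = stops$total_duration_s,
            n_visits = stops$n_visits
          )
        }
      }
    }
    if (config$verbose) {
      message(sprintf("algorithm '%s': %d runs (%.1f s)", algo,
                      length(config$bandwidths) * length(ids),
                      as.numeric(difftime(Sys.time(), ta, units = "secs"))))
    }
  }
  out <- structure(list(
    truth = track_set$truth,
    results = dplyr::bind_rows(res_rows),
    matches = dplyr::bind_rows(match_rows),
    stops = dplyr::bind_rows(stop_rows),
    config = config
  ), class = "experiment_result")
  if (!is.null(config$output_dir)) {
    write_experiment(out, config$output_dir)
  }
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Benchmark result: %d detection runs (%d tracks x {%s} m x %s)\n",
              nrow(x$results), length(unique(x$results$track_id)),
              paste(x$config$bandwidths, collapse = ", "),
              paste(unique(x$results$algo), collapse = "/")))
  tab <- table(x$results$algo, x$results$classification)
  print(tab)
  invisible(x)
}

write_experiment <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$results, file.path(dir, "results.csv"),
            row.names = FALSE, quote = FALSE)
  write_truth_csv(result$truth, file.path(dir, "truth.csv"))
  write_stops_csv(result$stops, file.path(dir, "stops.csv"))
  tabs <- make_tables(result)
  for (nm in names(tabs)) {
    write.csv(tabs[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Build the benchmark summary tables
#'
#' Aggregates an [run_experiment()] result into the study's report tables:
#' global classification percentages per bandwidth, on-target percentages per
#' bandwidth x noise bin, close-stop discrimination counts, bandwidth
#' sensitivity averages, full per-stratum metrics, and a six-criteria summary
#' scoreboard comparing the algorithms.
#'
#' @param result An `experiment_result`.
#' @return A named list of tibbles: `global`, `by_noise`, `close_stops`,
#'   `sensitivity`, `strata`, `summary`.
#' @export
make_tables <- function(result) {
  stopifnot(inherits(result, "experiment_result"))
  results <- result$results
  expected <- length(result$config$bandwidths) *
    length(unique(results$algo)) * length(unique(results$track_id))
  if (nrow(results) != expected) {
    got <- dplyr::count(results, .data$algo, .data$bandwidth_m)
    stop("incomplete result set: expected ", expected, " rows, got ",
         nrow(results), " (per-cell counts: ",
         paste(sprintf("%s@%g=%d", got$algo, got$bandwidth_m, got$n),
               collapse = ", "), ")")
  }
  global <- summarize_metrics(results, result$matches, by = "none")
  by_noise <- summarize_metrics(results, result$matches, by = "noise")
  close_stops <- close_stop_discrimination(results, result$truth)
  sens <- bandwidth_sensitivity(results)
  summary <- summarize_criteria(by_noise, global, close_stops)
  list(global = global, by_noise = by_noise, close_stops = close_stops,
       sensitivity = sens, strata = by_noise, summary = summary)
}

# Six-criteria scoreboard over the bandwidth x noise-bin combinations.
summarize_criteria <- function(by_noise, global, close_stops) {
  out <- lapply(unique(global$algo), function(a) {
    g <- global[global$algo == a, ]
    bn <- by_noise[by_noise$algo == a, ]
    cs <- close_stops[close_stops$algo == a, ]
    tibble::tibble(
      algo = a,
      n_combinations = nrow(bn),
      best_pct_on_target = max(g$pct_on_target),
      best_bandwidth_m = g$bandwidth_m[which.max(g$pct_on_target)],
      n_combos_on_target_ge_70 = sum(bn$pct_on_target >= 70),
      close_stop_total = sum(cs$n_on_target),
      n_combos_mean_stops_near_3 = sum(bn$mean_n_stops > 2.8 &
                                         bn$mean_n_stops < 3.2),
      n_combos_distance_lt_15m = sum(!is.na(bn$mean_distance) &
                                       bn$mean_distance < 15),
      n_combos_duration_err_lt_10 = sum(!is.na(bn$mean_duration_error) &
                                          abs(bn$mean_duration_error) < 10)
    )
  })
  dplyr::bind_rows(out)
}
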