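#' Parameters of the fixed-threshold (roaming radius) detector
#'
#' @param roaming_radius Distance threshold d, meters: a fix joins the current
#'   cluster while it stays within d of the cluster's running centroid.
#' @param min_stop_duration Minimal time span (last minus first fix) for a
#'   cluster to be emitted as a stop, seconds (default 300).
#' @param centroid_test If `FALSE` (default) membership is tested against the
#'   cluster's first fix (the anchor); if `TRUE`, against the running
#'   centroid. The anchor test reproduces the known failure profile of this
#'   algorithm family — cluster splitting under noise and false positives at
#'   large radii — whereas the centroid test is more forgiving.
#' @return A list of class `ft_params`.
#' @export
ft_params <- function(roaming_radius, min_stop_duration = 300,
                      centroid_test = FALSE) {
  stopifnot(roaming_radius > 0, min_stop_duration > 0)
  structure(list(roaming_radius = roaming_radius,
                 min_stop_duration = min_stop_duration,
                 centroid_test = isTRUE(centroid_test)),
            class = "ft_params")
}

#' @export
print.ft_params <- function(x, ...) {
  cat(sprintf(paste0("Fixed-threshold detector parameters: d = %g m, ",
                     "min stay = %g s, membership vs %s\n"),
              x$roaming_radius, x$min_stop_duration,
              if (x$centroid_test) "running centroid" else "first fix"))
  invisible(x)
}

#' Detect stops with the sequential time-distance algorithm
#'
#' Classical comparator: fixes are scanned in time order while a current
#' cluster with a running centroid is maintained. A fix within the roaming
#' radius of the centroid joins the cluster and updates the centroid;
#' otherwise the cluster is emitted as a stop if its time span reaches the
#' minimal duration, and a new cluster starts at the breaking fix (no fix is
#' discarded; a single excursion beyond the radius breaks the cluster). The
#' last cluster is flushed by the same rule at end of track. Emitted stops
#' whose centroids fall close together are not merged.
#'
#' @param track Planar track table for a single track.
#' @param params An [ft_params()] object.
#' @return A detected-stop tibble with the same schema as
#'   [detect_stops_kd()]; each stop carries exactly one visit.
#' @export
detect_stops_ft <- function(track, params) {
  stopifnot(inherits(params, "ft_params"))
  cl <- cpp_ft_cluster(track$t, track$x, track$y, params$roaming_radius,
                       params$min_stop_duration, params$centroid_test)
  if (nrow(cl) == 0) return(empty_stops())
  tibble::tibble(
    stop_id = seq_len(nrow(cl)), x = cl$x, y = cl$y,
    t_first = cl$t_start, t_last = cl$t_end,
    total_duration_s = cl$t_end - cl$t_start,
    n_visits = 1L, n_fixes = cl$n_fixes,
    visits = lapply(seq_len(nrow(cl)), function(k) {
      tibble::tibble(t_start = cl$t_start[k], t_end = cl$t_end[k],
                     n_fixes = cl$n_fixes[k])
    })
  )
}
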