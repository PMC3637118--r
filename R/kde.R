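#' Parameters of the kernel-density stop detector
#'
#' @param bandwidth Kernel bandwidth h, meters. The quartic kernel has compact
#'   support of radius h, and h is also the allocation radius when fixes are
#'   attached to peaks.
#' @param min_stop_duration Minimal total stay at a place to qualify as a
#'   stop, seconds (default 300 = 5 minutes).
#' @param cell_size Density grid resolution c, meters; defaults to
#'   `bandwidth / 10` clamped to the range 2-25 m, so location precision does
#'   not degrade at wide bandwidths. Must satisfy `0 < c <= bandwidth`.
#' @param merge_gap Visits to the same peak separated by at most this many
#'   seconds are merged into one visit spanning the gap (default 90).
#' @param min_peak_support Minimal number of fixes allocated to a peak for it
#'   to be kept (default 2); suppresses single-fix artifacts.
#' @param qualify How a peak qualifies as a stop: `"total"` (default) requires
#'   the summed duration of the peak's visits to reach `min_stop_duration`;
#'   `"visit"` requires a single merged visit that long.
#' @param suppress If `TRUE` (default), a peak lying within
#'   `max(bandwidth, suppress_floor)` of a denser peak is discarded
#'   (non-maximum suppression), so each detected place is the unique density
#'   maximum of its neighbourhood; spurious secondary maxima of one noisy
#'   point cloud are removed at the cost of merging true places closer than
#'   that radius.
#' @param suppress_floor Lower bound (m) on the suppression radius (default
#'   250): candidate places closer together than a single site's footprint
#'   are one place, whatever the bandwidth.
#' @param location Reported stop location: `"refined"` (default) runs a
#'   mean-shift iteration — the centroid of the allocated fixes within
#'   `min(bandwidth / 2, refine_radius)` of the current estimate, started at
#'   the density peak — giving sub-cell precision without the drag that
#'   distant trip fixes exert on a plain centroid; `"peak"` is the density
#'   maximum itself; `"centroid"` averages all allocated fixes.
#' @param refine_radius Upper bound (m) on the refinement window of the
#'   `"refined"` location (default 500).
#' @return A list of class `kd_params`.
#' @export
kd_params <- function(bandwidth, min_stop_duration = 300, cell_size = NULL,
                      merge_gap = 90, min_peak_support = 2,
                      qualify = c("total", "visit"), suppress = TRUE,
                      suppress_floor = 250,
                      location = c("refined", "peak", "centroid"),
                      refine_radius = 500) {
  if (is.null(cell_size)) cell_size <- max(min(bandwidth / 10, 25), 2)
  qualify <- match.arg(qualify)
  location <- match.arg(location)
  stopifnot(bandwidth > 0, cell_size > 0, cell_size <= bandwidth,
            min_stop_duration > 0, merge_gap >= 0, min_peak_support >= 1)
  structure(list(bandwidth = bandwidth,
                 min_stop_duration = min_stop_duration,
                 cell_size = cell_size, merge_gap = merge_gap,
                 min_peak_support = as.integer(min_peak_support),
                 qualify = qualify, suppress = isTRUE(suppress),
                 suppress_floor = suppress_floor,
                 location = location, refine_radius = refine_radius),
            class = "kd_params")
}

#' @export
print.kd_params <- function(x, ...) {
  cat(sprintf(paste0("Kernel-density detector parameters: h = %g m, ",
                     "cell = %g m, min stay = %g s, merge gap = %g s, ",
                     "min support = %d fixes\n"),
              x$bandwidth, x$cell_size, x$min_stop_duration, x$merge_gap,
              x$min_peak_support))
  invisible(x)
}

#' Kernel density surface of a set of fixes
#'
#' Sums a quartic (biweight) kernel, `K(d) = 3 / (pi h^2) (1 - d^2/h^2)^2` for
#' `d <= h` and 0 beyond, centered at every fix, evaluated at the centers of a
#' regular grid padded by at least one bandwidth beyond the fixes' bounding
#' box. Each fix contributes total mass 1, so the grid sum times the cell
#' area approximates the number of fixes.
#'
#' @param track Planar track table (or any data frame with `x`, `y`).
#' @param params A [kd_params()] object.
#' @return An object of class `density_surface`: origin (lower-left corner),
#'   cell size, grid dimensions, bandwidth and the density matrix (rows index
#'   northing, columns easting).
#' @export
compute_density_surface <- function(track, params) {
  stopifnot(inherits(params, "kd_params"))
  if (nrow(track) == 0) stop("cannot compute a density surface of no fixes")
  h <- params$bandwidth
  cs <- params$cell_size
  x0 <- min(track$x) - h - cs
  y0 <- min(track$y) - h - cs
  n_cols <- ceiling((max(track$x) + h + cs - x0) / cs)
  n_rows <- ceiling((max(track$y) + h + cs - y0) / cs)
  vals <- cpp_kde_surface(track$x, track$y, x0, y0, cs,
                          as.integer(n_rows), as.integer(n_cols), h)
  structure(list(origin = c(x0 = x0, y0 = y0), cell_size = cs,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 bandwidth = h, values = vals),
            class = "density_surface")
}

#' @export
print.density_surface <- function(x, ...) {
  cat(sprintf(paste0("Kernel density surface: %d x %d cells of %g m, ",
                     "h = %g m, origin (%.1f, %.1f)\n"),
              x$n_rows, x$n_cols, x$cell_size, x$bandwidth,
              x$origin[1], x$origin[2]))
  cat(sprintf("  max density %.3g /m^2, %d nonzero cells\n",
              max(x$values), sum(x$values > 0)))
  invisible(x)
}

surface_cell_center <- function(surface, i, j) {
  # i, j are 0-based (possibly fractional, for plateau centroids)
  cbind(x = surface$origin[["x0"]] + (j + 0.5) * surface$cell_size,
        y = surface$origin[["y0"]] + (i + 0.5) * surface$cell_size)
}

#' Extract local density maxima (peaks)
#'
#' A grid cell is a peak when its density is positive and no 8-neighbour
#' exceeds it; connected plateaus of exactly equal density collapse to a
#' single peak at the plateau's cell centroid. Peaks are ordered by
#' decreasing density (ties by row-major cell position) and ids assigned in
#' that order.
#'
#' @param surface A [compute_density_surface()] result.
#' @param suppress_radius Optional non-maximum-suppression radius in meters:
#'   peaks within this distance of a denser peak are dropped (greedy, in
#'   decreasing density order). `NULL` keeps every local maximum.
#' @return A tibble `peak_id, x, y, density` (possibly empty).
#' @export
extract_peaks <- function(surface, suppress_radius = NULL) {
  stopifnot(inherits(surface, "density_surface"))
  pk <- cpp_find_peaks(surface$values)
  if (nrow(pk) == 0) {
    return(tibble::tibble(peak_id = integer(), x = numeric(),
                          y = numeric(), density = numeric()))
  }
  ctr <- surface_cell_center(surface, pk$i, pk$j)
  x <- ctr[, "x"]
  y <- ctr[, "y"]
  if (!is.null(suppress_radius) && nrow(pk) > 1) {
    keep <- cpp_nms(x, y, suppress_radius)
    pk <- pk[keep, ]
    x <- x[keep]
    y <- y[keep]
  }
  tibble::tibble(peak_id = seq_len(nrow(pk)), x = x, y = y,
                 density = pk$density)
}

#' Allocate fixes to peaks or trip segments
#'
#' Each fix is labeled with the id of the nearest peak if that Euclidean
#' distance is at most the bandwidth, and `NA` (trip) otherwise. Exact ties
#' go to the lowest peak id.
#'
#' @param track Planar track table.
#' @param peaks Peak table from [extract_peaks()].
#' @param params A [kd_params()] object.
#' @return An integer vector of peak ids aligned with the track's fixes, `NA`
#'   marking trip fixes.
#' @export
assign_fixes <- function(track, peaks, params) {
  if (nrow(peaks) == 0) return(rep(NA_integer_, nrow(track)))
  cpp_assign_nearest(track$x, track$y, peaks$x, peaks$y, params$bandwidth)
}

#' Build per-peak visit timetables from fix labels
#'
#' Maximal runs of consecutive fixes sharing a peak label become visits
#' (start/end = first/last fix time of the run). Consecutive visits to the
#' same peak separated by a gap of at most `merge_gap` seconds are merged
#' into a single visit spanning the gap.
#'
#' @param labels Integer peak labels aligned with `times` (`NA` = trip).
#' @param times Fix timestamps, seconds.
#' @param params A [kd_params()] object.
#' @return A tibble `peak_id, t_start, t_end, n_fixes`, ordered by peak then
#'   start time.
#' @export
build_visits <- function(labels, times, params) {
  stopifnot(length(labels) == length(times))
  empty <- tibble::tibble(peak_id = integer(), t_start = numeric(),
                          t_end = numeric(), n_fixes = integer())
  if (length(labels) == 0) return(empty)
  r <- rle(ifelse(is.na(labels), -1L, labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values >= 0L
  if (!any(keep)) return(empty)
  pk <- r$values[keep]
  ts <- times[starts[keep]]
  te <- times[ends[keep]]
  nf <- r$lengths[keep]
  # group runs by peak (runs stay in time order within each peak) and merge
  # consecutive runs of the same peak separated by gaps <= merge_gap
  o <- order(pk, ts)
  pk <- pk[o]; ts <- ts[o]; te <- te[o]; nf <- nf[o]
  n <- length(pk)
  new_visit <- c(TRUE, pk[-1] != pk[-n] | (ts[-1] - te[-n]) > params$merge_gap)
  first <- which(new_visit)
  last <- c(first[-1] - 1L, n)
  tibble::tibble(peak_id = pk[first], t_start = ts[first], t_end = te[last],
                 n_fixes = as.integer(rowsum(nf, cumsum(new_visit))[, 1]))
}

empty_stops <- function() {
  tibble::tibble(stop_id = integer(), x = numeric(), y = numeric(),
                 t_first = numeric(), t_last = numeric(),
                 total_duration_s = numeric(), n_visits = integer(),
                 n_fixes = integer(), visits = list())
}

#' Detect stops with the kernel-density algorithm
#'
#' The full chain: density surface, peak extraction, nearest-peak fix
#' allocation, visit timetable, then a peak is kept as a stop when its total
#' visit duration reaches `min_stop_duration` and at least
#' `min_peak_support` fixes were allocated to it. The reported stop location
#' is the centroid of all fixes allocated to the peak (sub-cell refinement of
#' the peak position). Stops come back in chronological order of first visit.
#'
#' @param track Planar track table for a single track.
#' @param params A [kd_params()] object.
#' @return A tibble with one row per detected stop: `stop_id, x, y, t_first,
#'   t_last, total_duration_s, n_visits, n_fixes` and a `visits` list-column
#'   of per-stop visit tables.
#' @export
detect_stops_kd <- function(track, params) {
  stopifnot(inherits(params, "kd_params"))
  surface <- compute_density_surface(track, params)
  peaks <- extract_peaks(
    surface,
    suppress_radius = if (params$suppress) {
      max(params$bandwidth, params$suppress_floor)
    }
  )
  if (nrow(peaks) == 0) return(empty_stops())
  labels <- assign_fixes(track, peaks, params)
  visits <- build_visits(labels, track$t, params)
  if (nrow(visits) == 0) return(empty_stops())
  per_peak <- dplyr::summarise(
    dplyr::group_by(visits, .data$peak_id),
    t_first = min(.data$t_start), t_last = max(.data$t_end),
    total_duration_s = sum(.data$t_end - .data$t_start),
    max_visit_s = max(.data$t_end - .data$t_start),
    n_visits = dplyr::n(), n_fixes = sum(.data$n_fixes),
    .groups = "drop"
  )
  qual_dur <- if (params$qualify == "visit") per_peak$max_visit_s else
    per_peak$total_duration_s
  keep <- qual_dur >= params$min_stop_duration &
    per_peak$n_fixes >= params$min_peak_support
  per_peak <- per_peak[keep, ]
  if (nrow(per_peak) == 0) return(empty_stops())
  idx <- match(per_peak$peak_id, peaks$peak_id)
  per_peak$x <- peaks$x[idx]
  per_peak$y <- peaks$y[idx]
  if (params$location != "peak") {
    r_max <- if (params$location == "refined") {
      min(params$bandwidth / 2, params$refine_radius)
    } else {
      Inf
    }
    for (k in seq_len(nrow(per_peak))) {
      alloc <- !is.na(labels) & labels == per_peak$peak_id[k]
      if (!is.finite(r_max)) {
        per_peak$x[k] <- mean(track$x[alloc])
        per_peak$y[k] <- mean(track$y[alloc])
        next
      }
      # mean-shift within the place footprint: recentre on the local centroid
      # until stable, so a displaced grid peak slides onto the fix cloud core
      cx <- per_peak$x[k]
      cy <- per_peak$y[k]
      for (it in 1:8) {
        sel <- alloc & (track$x - cx)^2 + (track$y - cy)^2 <= r_max^2
        if (!any(sel)) break
        nx <- mean(track$x[sel])
        ny <- mean(track$y[sel])
        moved <- (nx - cx)^2 + (ny - cy)^2
        cx <- nx
        cy <- ny
        if (moved < 1) break
      }
      per_peak$x[k] <- cx
      per_peak$y[k] <- cy
    }
  }
  per_peak <- per_peak[order(per_peak$t_first), ]
  per_peak$visits <- lapply(per_peak$peak_id, function(p) {
    visits[visits$peak_id == p, c("t_start", "t_end", "n_fixes")]
  })
  per_peak$stop_id <- seq_len(nrow(per_peak))
  per_peak[, c("stop_id", "x", "y", "t_first", "t_last", "total_duration_s",
               "n_visits", "n_fixes", "visits")]
}
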