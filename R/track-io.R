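#' @useDynLib trackstops, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom stats rnorm runif sd approx
#' @importFrom utils head read.csv write.csv
NULL

EARTH_RADIUS_M <- 6371008.8

#' Validate a table of GPS fixes
#'
#' A track table holds one row per fix with columns `track_id`, `t` (epoch
#' seconds, UTC), and either planar coordinates `x`, `y` (meters) or
#' geographic `lon`, `lat` (degrees). Timestamps must be strictly increasing
#' within each track and every track needs at least two fixes.
#'
#' @param tracks A data frame of fixes.
#' @param coords `"planar"` to require `x`/`y`, `"geo"` to require
#'   `lon`/`lat`, `"any"` for either.
#' @return `tracks`, invisibly, as a tibble.
#' @export
validate_tracks <- function(tracks, coords = c("any", "planar", "geo")) {
  coords <- match.arg(coords)
  tracks <- tibble::as_tibble(tracks)
  need <- switch(coords,
    planar = c("track_id", "t", "x", "y"),
    geo = c("track_id", "t", "lon", "lat"),
    any = c("track_id", "t")
  )
  miss <- setdiff(need, names(tracks))
  if (length(miss) > 0) {
    stop("track table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (coords == "any" &&
      !(all(c("x", "y") %in% names(tracks)) ||
        all(c("lon", "lat") %in% names(tracks)))) {
    stop("track table needs either x/y or lon/lat coordinates")
  }
  num_cols <- intersect(c("t", "x", "y", "lon", "lat"), names(tracks))
  for (cl in num_cols) {
    if (!all(is.finite(tracks[[cl]]))) {
      stop("non-finite values in column '", cl, "'")
    }
  }
  for (id in unique(tracks$track_id)) {
    tt <- tracks$t[tracks$track_id == id]
    if (length(tt) < 2) stop("track '", id, "' has fewer than 2 fixes")
    if (any(diff(tt) <= 0)) {
      stop("track '", id, "' has non-increasing timestamps")
    }
  }
  invisible(tracks)
}

# Drop duplicate-timestamp fixes within each track, keeping the first.
drop_duplicate_times <- function(tracks) {
  dup <- unlist(lapply(split(seq_len(nrow(tracks)), tracks$track_id),
                       function(ix) ix[duplicated(tracks$t[ix])]),
                use.names = FALSE)
  if (length(dup) > 0) {
    warning(length(dup), " fix(es) with duplicate timestamps dropped ",
            "(first occurrence kept)")
    tracks <- tracks[-dup, , drop = FALSE]
  }
  tracks
}

parse_times <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  suppressWarnings(num <- as.numeric(x))
  if (!anyNA(num)) return(num)
  tm <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  bad <- is.na(tm) & !is.na(x)
  if (any(bad)) {
    stop("unparseable timestamp(s), e.g. '", x[which(bad)[1]],
         "' (expected ISO-8601 or epoch seconds)")
  }
  as.numeric(tm)
}

format_iso <- function(t) {
  op <- options(digits.secs = 3, OutDec = ".")
  on.exit(options(op))
  format(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%OS3Z")
}

#' Read GPS tracks from a GPX 1.1 file
#'
#' One track per `<trk>` element; fixes come from `trkpt` latitude/longitude
#' attributes and their `<time>` children. Fixes are sorted by time; duplicate
#' timestamps are dropped with a warning and any remaining non-monotone time
#' sequence is an error.
#'
#' @param path Path to a GPX file.
#' @return A tibble of fixes with columns `track_id`, `t`, `lon`, `lat`.
#' @export
read_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  trks <- xml2::xml_find_all(doc, ".//trk")
  if (length(trks) == 0) stop("no <trk> elements in '", path, "'")
  out <- vector("list", length(trks))
  for (k in seq_along(trks)) {
    nm <- xml2::xml_text(xml2::xml_find_first(trks[[k]], "./name"))
    id <- if (is.na(nm) || !nzchar(nm)) sprintf("trk_%03d", k) else nm
    pts <- xml2::xml_find_all(trks[[k]], ".//trkpt")
    if (length(pts) == 0) stop("track '", id, "' has no trkpt elements")
    lat <- as.numeric(xml2::xml_attr(pts, "lat"))
    lon <- as.numeric(xml2::xml_attr(pts, "lon"))
    tnode <- xml2::xml_find_first(pts, "./time")
    traw <- xml2::xml_text(tnode)
    if (anyNA(traw)) {
      stop("track '", id, "': trkpt missing timestamp")
    }
    tm <- as.POSIXct(traw, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
    if (anyNA(tm)) stop("track '", id, "': unparseable <time> value")
    o <- order(tm)
    df <- tibble::tibble(track_id = id, t = as.numeric(tm)[o],
                         lon = lon[o], lat = lat[o])
    df <- drop_duplicate_times(df)
    if (any(diff(df$t) <= 0)) {
      stop("track '", id, "': non-monotone timestamps")
    }
    out[[k]] <- df
  }
  validate_tracks(dplyr::bind_rows(out), coords = "geo")
}

#' Write GPS tracks to a GPX 1.1 file
#'
#' @param tracks A geographic track table (`track_id`, `t`, `lon`, `lat`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gpx <- function(tracks, path) {
  tracks <- validate_tracks(tracks, coords = "geo")
  doc <- xml2::xml_new_root("gpx", version = "1.1", creator = "trackstops",
                            xmlns = "http://www.topografix.com/GPX/1/1")
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, ]
    trk <- xml2::xml_add_child(doc, "trk")
    xml2::xml_add_child(trk, "name", id)
    seg <- xml2::xml_add_child(trk, "trkseg")
    iso <- format(as.POSIXct(round(tr$t), origin = "1970-01-01", tz = "UTC"),
                  "%Y-%m-%dT%H:%M:%SZ")
    for (i in seq_len(nrow(tr))) {
      pt <- xml2::xml_add_child(seg, "trkpt",
                                lat = sprintf("%.8f", tr$lat[i]),
                                lon = sprintf("%.8f", tr$lon[i]))
      xml2::xml_add_child(pt, "time", iso[i])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Project geographic fixes to a local planar frame
#'
#' Applies a spherical azimuthal-equidistant projection centered on a
#' reference point, yielding easting/northing in meters. Distances from the
#' reference are exact great-circle distances; pairwise distances between
#' points within ~10 km of the reference are preserved to well under 0.1%.
#' All detection math in this package operates on these planar meters.
#'
#' @param tracks Geographic track table (`lon`, `lat` in degrees).
#' @param ref_lon,ref_lat Projection center; defaults to the mean fix.
#' @return The table with `x`, `y` (m) added and the reference stored in
#'   attributes `ref_lon`, `ref_lat`.
#' @export
project_to_plane <- function(tracks, ref_lon = NULL, ref_lat = NULL) {
  tracks <- validate_tracks(tracks, coords = "geo")
  if (is.null(ref_lon)) ref_lon <- mean(tracks$lon)
  if (is.null(ref_lat)) ref_lat <- mean(tracks$lat)
  d2r <- pi / 180
  lam <- tracks$lon * d2r
  phi <- tracks$lat * d2r
  lam0 <- ref_lon * d2r
  phi0 <- ref_lat * d2r
  dl <- lam - lam0
  # great-circle angle (haversine) and forward azimuth from the reference
  a <- sin((phi - phi0) / 2)^2 + cos(phi0) * cos(phi) * sin(dl / 2)^2
  cang <- 2 * asin(pmin(1, sqrt(a)))
  az <- atan2(sin(dl) * cos(phi), cos(phi0) * sin(phi) -
                sin(phi0) * cos(phi) * cos(dl))
  dist <- EARTH_RADIUS_M * cang
  if (any(dist > 100e3)) {
    stop("fix(es) farther than 100 km from the reference point; ",
         "local planar projection invalid")
  }
  tracks$x <- dist * sin(az)
  tracks$y <- dist * cos(az)
  attr(tracks, "ref_lon") <- ref_lon
  attr(tracks, "ref_lat") <- ref_lat
  tracks
}

#' Recover geographic coordinates from local planar ones
#'
#' Inverse of [project_to_plane()] for the same reference point.
#'
#' @param tracks Planar track table (`x`, `y` in meters).
#' @param ref_lon,ref_lat Projection center used for the forward projection.
#' @return The table with `lon`, `lat` columns set.
#' @export
unproject_from_plane <- function(tracks, ref_lon, ref_lat) {
  tracks <- validate_tracks(tracks, coords = "planar")
  d2r <- pi / 180
  lam0 <- ref_lon * d2r
  phi0 <- ref_lat * d2r
  dist <- sqrt(tracks$x^2 + tracks$y^2)
  cang <- dist / EARTH_RADIUS_M
  az <- atan2(tracks$x, tracks$y)
  phi <- asin(sin(phi0) * cos(cang) + cos(phi0) * sin(cang) * cos(az))
  lam <- lam0 + atan2(sin(az) * sin(cang) * cos(phi0),
                      cos(cang) - sin(phi0) * sin(phi))
  tracks$lon <- lam / d2r
  tracks$lat <- phi / d2r
  # the projection center itself maps back exactly
  at0 <- dist == 0
  tracks$lon[at0] <- ref_lon
  tracks$lat[at0] <- ref_lat
  tracks
}

#' Read and write planar track CSV files
#'
#' The track CSV schema is `track_id,t,x,y` with `t` as ISO-8601 (written with
#' millisecond precision) or epoch seconds. Reads enforce strictly increasing
#' timestamps per track; duplicate timestamps are dropped with a warning.
#'
#' @param path CSV path.
#' @return `read_track_csv()`: a tibble of fixes; an empty file with only the
#'   header yields a zero-row tibble.
#' @export
read_track_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = NA)
  need <- c("track_id", "t", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("track CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  df$track_id <- as.character(df$track_id)
  df$t <- parse_times(df$t)
  df <- tibble::as_tibble(df[need])
  if (nrow(df) == 0) return(df)
  df <- drop_duplicate_times(df)
  for (id in unique(df$track_id)) {
    tt <- df$t[df$track_id == id]
    if (any(diff(tt) < 0)) {
      stop("track '", id, "': decreasing timestamps in '", path, "'")
    }
  }
  validate_tracks(df, coords = "planar")
  df
}

#' @rdname read_track_csv
#' @param tracks Planar track table to write.
#' @export
write_track_csv <- function(tracks, path) {
  tracks <- validate_tracks(tracks, coords = "planar")
  out <- data.frame(track_id = tracks$track_id, t = format_iso(tracks$t),
                    x = sprintf("%.6f", tracks$x),
                    y = sprintf("%.6f", tracks$y))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write ground-truth stop tables
#'
#' Schema: `track_id,stop_id,cx,cy,t_arrive,t_depart,noise_m` — the generating
#' stop centers, realized arrival/departure times (epoch seconds) and the
#' per-track positional noise magnitude (per-axis Gaussian SD, meters).
#'
#' @param path CSV path.
#' @return A tibble with the truth schema.
#' @export
read_truth_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "stop_id", "cx", "cy", "t_arrive", "t_depart",
            "noise_m")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("truth CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- tibble::as_tibble(df[need])
  df$track_id <- as.character(df$track_id)
  validate_truth(df)
  df
}

#' @rdname read_truth_csv
#' @param truth Truth table to write.
#' @export
write_truth_csv <- function(truth, path) {
  validate_truth(truth)
  truth <- truth[order(truth$track_id, truth$stop_id), ]
  write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_truth_csv
#' @param truth Truth table.
#' @export
validate_truth <- function(truth) {
  if (any(truth$t_depart <= truth$t_arrive)) {
    stop("truth table has stop(s) with t_depart <= t_arrive")
  }
  if (any(truth$noise_m < 0)) stop("negative noise_m in truth table")
  for (id in unique(truth$track_id)) {
    st <- truth[truth$track_id == id, ]
    st <- st[order(st$stop_id), ]
    if (nrow(st) > 1 &&
        any(st$t_arrive[-1] < st$t_depart[-nrow(st)])) {
      stop("track '", id, "': overlapping or out-of-order stop windows")
    }
  }
  invisible(truth)
}

#' Read and write detected-stop tables
#'
#' Schema: `algo,bandwidth_m,track_id,stop_id,x,y,total_duration_s,n_visits`.
#' Rows are written sorted by (algo, bandwidth_m, track_id, stop_id) so output
#' files are deterministic.
#'
#' @param stops Detected-stop table (one row per stop).
#' @param path CSV path.
#' @export
write_stops_csv <- function(stops, path) {
  need <- c("algo", "bandwidth_m", "track_id", "stop_id", "x", "y",
            "total_duration_s", "n_visits")
  miss <- setdiff(need, names(stops))
  if (length(miss) > 0) {
    stop("stops table missing column(s): ", paste(miss, collapse = ", "))
  }
  stops <- stops[need]
  stops <- stops[order(stops$algo, stops$bandwidth_m, stops$track_id,
                       stops$stop_id), ]
  write.csv(stops, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stops_csv
#' @export
read_stops_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("algo", "bandwidth_m", "track_id", "stop_id", "x", "y",
            "total_duration_s", "n_visits")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("stops CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  tibble::as_tibble(df[need])
}
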