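test_that("GPX round trip preserves fixes within format precision", {
  tracks <- tibble::tibble(
    track_id = rep(c("a", "b"), each = 3),
    t = c(0, 10, 20, 5, 15, 25) + 1.6e9,
    lon = c(2.3501, 2.3502, 2.3503, 2.3601, 2.3602, 2.3603),
    lat = c(48.8501, 48.8502, 48.8503, 48.8401, 48.8402, 48.8403)
  )
  path <- withr::local_tempfile(fileext = ".gpx")
  write_gpx(tracks, path)
  back <- read_gpx(path)
  expect_equal(back$track_id, tracks$track_id)
  expect_equal(back$t, tracks$t, tolerance = 1)
  expect_equal(back$lon, tracks$lon, tolerance = 1e-7)
  expect_equal(back$lat, tracks$lat, tolerance = 1e-7)
})

test_that("GPX reading enforces the contract", {
  path <- withr::local_tempfile(fileext = ".gpx")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<gpx version="1.1"><trk><name>x</name><trkseg>',
    '<trkpt lat="48.85" lon="2.35"><time>2020-01-01T00:00:00Z</time></trkpt>',
    '<trkpt lat="48.86" lon="2.36"></trkpt>',
    "</trkseg></trk></gpx>"
  ), path)
  expect_error(read_gpx(path), "missing timestamp")

  writeLines(c(
    '<?xml version="1.0"?>',
    '<gpx version="1.1"><trk><name>x</name><trkseg>',
    '<trkpt lat="48.85" lon="2.35"><time>2020-01-01T00:00:10Z</time></trkpt>',
    '<trkpt lat="48.86" lon="2.36"><time>2020-01-01T00:00:00Z</time></trkpt>',
    "</trkseg></trk></gpx>"
  ), path)
  # unordered but distinct times are sorted, not an error
  expect_equal(nrow(read_gpx(path)), 2)
})

test_that("projection matches a haversine oracle and round-trips", {
  skip_if_not_installed("geosphere")
  ref <- c(lon = 2.35, lat = 48.85)
  pts <- tibble::tibble(
    track_id = "a", t = seq(0, 50, 10),
    lon = ref[["lon"]] + c(0, 0.001, -0.002, 0.01, 0.03, -0.02),
    lat = ref[["lat"]] + c(0, 0.001, 0.002, -0.01, 0.02, 0.015)
  )
  pl <- project_to_plane(pts, ref[["lon"]], ref[["lat"]])
  expect_equal(pl$x[1], 0, tolerance = 1e-9)
  expect_equal(pl$y[1], 0, tolerance = 1e-9)

  # a point 0.001 deg due north of the reference is ~111.2 m away
  north <- project_to_plane(
    tibble::tibble(track_id = "n", t = c(0, 10),
                   lon = ref[["lon"]], lat = ref[["lat"]] + c(0, 0.001)),
    ref[["lon"]], ref[["lat"]]
  )
  expect_equal(north$y[2], 111.2, tolerance = 0.1)
  expect_lt(abs(north$x[2]), 0.01)

  # distance from the reference is exact; pairwise distances within 0.1%
  d_ref <- geosphere::distHaversine(cbind(pts$lon, pts$lat), ref,
                                    r = 6371008.8)
  expect_equal(sqrt(pl$x^2 + pl$y^2), d_ref, tolerance = 1e-6)
  for (i in 2:5) {
    gc <- geosphere::distHaversine(c(pts$lon[i], pts$lat[i]),
                                   c(pts$lon[i + 1], pts$lat[i + 1]),
                                   r = 6371008.8)
    eu <- sqrt((pl$x[i] - pl$x[i + 1])^2 + (pl$y[i] - pl$y[i + 1])^2)
    expect_equal(eu, gc, tolerance = 1e-3)
  }

  back <- unproject_from_plane(pl, ref[["lon"]], ref[["lat"]])
  expect_equal(back$lon, pts$lon, tolerance = 1e-7)
  expect_equal(back$lat, pts$lat, tolerance = 1e-7)

  far <- tibble::tibble(track_id = "f", t = c(0, 10),
                        lon = ref[["lon"]] + c(0, 2), lat = ref[["lat"]])
  expect_error(project_to_plane(far, ref[["lon"]], ref[["lat"]]), "100 km")
})

test_that("track CSV round trip is lossless and validates timestamps", {
  tracks <- tibble::tibble(
    track_id = rep(c("t1", "t2"), each = 4),
    t = c(0, 10, 20.5, 30, 100, 110, 120, 130) + 1.6e9,
    x = rnorm(8, 1000, 200), y = rnorm(8, 2000, 200)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_track_csv(tracks, path)
  back <- read_track_csv(path)
  expect_equal(back$track_id, tracks$track_id)
  expect_equal(back$t, tracks$t, tolerance = 1e-3)
  expect_equal(back$x, tracks$x, tolerance = 1e-6)
  expect_equal(back$y, tracks$y, tolerance = 1e-6)

  # decreasing timestamps within a track are an error
  writeLines(c("track_id,t,x,y", "a,100,0,0", "a,50,1,1"), path)
  expect_error(read_track_csv(path), "decreasing")

  # missing column is an error
  writeLines(c("track_id,t,x", "a,100,0"), path)
  expect_error(read_track_csv(path), "missing column")

  # an empty file with a header yields an empty collection
  writeLines("track_id,t,x,y", path)
  expect_equal(nrow(read_track_csv(path)), 0)
})

test_that("duplicate timestamps are dropped keeping the first, with warning", {
  tracks <- tibble::tibble(track_id = "a", t = c(0, 10, 10, 20),
                           x = c(0, 1, 99, 3), y = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  suppressWarnings(write_track_csv(validate_tracks(
    tibble::tibble(track_id = "a", t = c(0, 10, 20), x = c(0, 1, 3), y = 0),
    "planar"
  ), path))
  writeLines(c("track_id,t,x,y", "a,0,0,0", "a,10,1,0", "a,10,99,0",
               "a,20,3,0"), path)
  expect_warning(back <- read_track_csv(path), "duplicate")
  expect_equal(back$x, c(0, 1, 3))
})

test_that("truth and stops CSV round trips enforce their schemas", {
  truth <- tibble::tibble(
    track_id = rep(sprintf("tr%02d", 1:5), each = 3),
    stop_id = rep(1:3, 5),
    cx = runif(15, 0, 6000), cy = runif(15, 0, 6000),
    t_arrive = rep(c(0, 2000, 5000), 5),
    t_depart = rep(c(1000, 4000, 8000), 5),
    noise_m = rep(runif(5, 0, 200), each = 3)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_truth_csv(truth, path)
  back <- read_truth_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(truth), tolerance = 1e-6)

  bad <- truth
  bad$t_depart[1] <- bad$t_arrive[1]
  expect_error(write_truth_csv(bad, path), "t_depart")

  stops <- tibble::tibble(
    algo = c("kd", "ft", "kd"), bandwidth_m = c(200, 100, 50),
    track_id = "tr01", stop_id = 1L,
    x = 1:3, y = 4:6, total_duration_s = 600, n_visits = 1L
  )
  write_stops_csv(stops, path)
  back <- read_stops_csv(path)
  # deterministic sort by (algo, bandwidth, track, stop)
  expect_equal(back$algo, c("ft", "kd", "kd"))
  expect_equal(back$bandwidth_m, c(100, 50, 200))
})
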