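Package: trackstops
Title: Kernel-Based Activity Stop Detection for Raw GPS Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects activity locations (stops) in raw GPS trajectories with a
    global kernel-density algorithm: a quartic-kernel density surface is built
    from the fixes, local maxima are extracted as candidate places, fixes are
    allocated to the nearest peak, and a timetable of visits is derived with a
    minimum-stay filter. A classical sequential time-distance (roaming radius)
    comparator, a controlled synthetic-track generator with known stops and
    Gaussian positional noise, and a full performance-indicator suite (global
    classification, spatial and temporal accuracy, close-stop discrimination,
    bandwidth sensitivity) support end-to-end benchmarking of stop-detection
    algorithms. Intended for exposure-assessment preprocessing in health and
    place research.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    geosphere,
    jsonlite,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
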