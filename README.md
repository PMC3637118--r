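# trackstops

Raw GPS tracks are a poor substrate for health and place research: what
epidemiological models need is the sequence of *activity locations* — the
places a person stopped at, and for how long — not a cloud of noisy fixes.
`trackstops` extracts that sequence. Its core is a global kernel-density
stop-detection algorithm: instead of scanning fixes one by one, it

1. builds a density surface over all fixes of a track with a compact-support
   **quartic (biweight) kernel**, `K(d) = 3/(πh²)(1 − d²/h²)²` for `d ≤ h`,
   where the bandwidth `h` is the algorithm's spatial scale;
2. extracts **local maxima** of the surface as candidate places, discarding
   secondary maxima within `max(h, 250 m)` of a denser one;
3. allocates each fix to its nearest peak (within `h`) or to a trip segment;
4. derives a **timetable of visits** per peak (maximal runs of consecutive
   fixes, merged across gaps ≤ 90 s) and keeps the peaks whose total stay
   reaches the minimal stop duration (5 min by default).

Because the kernel averages over the whole fix cloud, detection degrades
gracefully with GPS noise, whereas the classical sequential time–distance
algorithm (also provided, as the comparator `detect_stops_ft()`: a cluster
grows while fixes stay within a roaming radius `d` of its first fix, and is
kept if it spans the minimal duration) either fragments a stay or swallows
neighbouring places as `d` varies.

The package also ships the evaluation apparatus for benchmarking such
detectors end-to-end with no external data:

- a **synthetic track generator** (`generate_track_set()`): 750 tracks by
  default, three stops each placed uniformly in a 6 km square, dwell times
  drawn from three duration categories ([6, 20] min, [20, 120] min,
  [2, 6] h), straight-line trips at 36 km/h, fixes every 10 s, and isotropic
  Gaussian positional noise whose per-axis SD is drawn once per track from
  U[0, 200] m — so ground truth (stop centres, arrival/departure times,
  noise level) is known exactly;
- **performance indicators** (`classify_track()`, `match_stops()`,
  `summarize_metrics()`, `close_stop_discrimination()`,
  `bandwidth_sensitivity()`): on-target / false-negative / false-positive
  classification with a 1 km outlier rule, spatial accuracy (distance to the
  closest true stop), temporal accuracy ((Δ_found − Δ_true)/Δ_true),
  discrimination of stops closer than 800 m, and the per-noise-bin range of
  bandwidths that still recover the right stop count;
- an **experiment driver** (`run_experiment()`, `make_tables()`) that runs
  both algorithms at bandwidths {10, 50, 100, 200, 500, 1000} m over the
  whole set (2 × 4,500 runs) and aggregates the summary tables.

GPX 1.1 and CSV readers/writers plus a local azimuthal-equidistant
projection (`read_gpx()`, `project_to_plane()`, `read_track_csv()`, ...)
connect the detectors to real-world tracks; all detection math runs in
planar meters.

## Worked example

```r
library(trackstops)

cfg   <- generator_config(n_tracks = 1, master_seed = 42)
plan  <- sample_stop_plan(cfg, seed = 7)       # 3 stops, noise SD 154.6 m
path  <- build_noiseless_path(plan, cfg, track_id = "demo")
set.seed(7)
track <- apply_noise(path$track, plan$noise_m)

stops <- detect_stops_kd(track, kd_params(bandwidth = 200))
stops[, c("stop_id", "x", "y", "total_duration_s", "n_visits", "n_fixes")]
#>   stop_id     x     y total_duration_s n_visits n_fixes
#> 1       1 5914.  425.            13820        1     805
#> 2       2 2406. 1492.             2290        1     124
#> 3       3  746. 4739.             2580        1     155

match_stops(stops, path$truth)
#>   stop_id true_stop_id distance duration_error
#> 1       1            1     20.5       0.000645
#> 2       2            2     35.5       0.0267
#> 3       3            3     53.4      -0.00342
```

Despite a positional noise SD of ~155 m per axis, the 200 m bandwidth
recovers all three stops: locations land within a few tens of meters of the
true centres (against fix scatter of ~200 m radial) and stay durations are
estimated within ~3%. The same track defeats the fixed-threshold comparator
at most radii — `detect_stops_ft(track, ft_params(200))` fragments the long
dwells into spurious extra stops.

A full factorial benchmark with summary tables lands in `out/` with:

```r
run_experiment(experiment_config(generator_config(master_seed = 1),
                                 output_dir = "out"))
```

A thin command-line wrapper over these functions is installed at
`inst/cli/trackstops.R` (subcommands `generate`, `detect`, `evaluate`,
`replicate`).

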