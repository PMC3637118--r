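---
title: "Kernel-based activity stop detection: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-based activity stop detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackstops)
```

## The problem

A GPS logger worn through a day produces thousands of timestamped fixes.
Exposure assessment and activity-space analysis need something sparser and
more meaningful: the list of places where the person actually stayed — an
*activity location* being a spot where at least five minutes were spent —
together with a timetable of visits. Extracting that list is a clustering
problem complicated by positional noise: a stationary receiver scatters its
fixes over tens to hundreds of meters depending on the environment, and a
detector tuned for clean signals either shreds a noisy stay into fragments
or, tuned coarsely, fuses neighbouring places.

`trackstops` implements two detectors over planar tracks (`t`, `x`, `y` in
epoch seconds and meters):

* `detect_stops_kd()` — the kernel-density algorithm, which treats the track
  globally;
* `detect_stops_ft()` — the classical sequential time–distance comparator.

## The kernel-density model

The track's fixes are treated as a sample from a spatial intensity: places
where time was spent accumulate many fixes, trips leave thin trails. The
intensity is estimated by kernel density estimation with the quartic
(biweight) kernel

$$K_h(d) = \frac{3}{\pi h^2}\Big(1 - \frac{d^2}{h^2}\Big)^2, \qquad d \le h,$$

summed over fixes and evaluated on a regular grid. The kernel has compact
support, so the surface is exactly zero beyond `h` of every fix, and each
fix contributes unit mass (the grid sum times the cell area equals the fix
count to well under 1%, which the tests assert). The bandwidth `h` is the
algorithm's single spatial scale: it is the smoothing radius, and also the
radius within which fixes are later allocated to a detected place.

The full chain, with its tunable parameters (all in `kd_params()`):

| parameter | default | role |
|---|---|---|
| `bandwidth` (m) | — | kernel support radius, allocation radius |
| `min_stop_duration` (s) | 300 | minimal total stay to qualify as a stop |
| `cell_size` (m) | `h/10`, clamped to [2, 25] | grid resolution |
| `merge_gap` (s) | 90 | visit fragments closer than this merge |
| `min_peak_support` (fixes) | 2 | suppresses single-fix artifacts |
| `suppress_floor` (m) | 250 | minimal non-maximum-suppression radius |
| `refine_radius` (m) | 500 | cap on the location-refinement window |

1. **Surface** (`compute_density_surface()`): grid padded one bandwidth
   beyond the fixes' bounding box. The cell size tracks the bandwidth
   (`h/10`) but is clamped to at most 25 m so that the position of a maximum
   is never quantized coarsely at wide bandwidths, and to at least 2 m to
   bound work at narrow ones.
2. **Peaks** (`extract_peaks()`): cells that are positive and not exceeded
   by any 8-neighbour; plateaus of exactly equal value collapse to their
   cell centroid. Peaks are ordered by decreasing density (ties broken by
   row-major cell position — determinism matters for reproducible ids), then
   greedily thinned: a peak within `max(h, 250 m)` of a denser retained peak
   is discarded. This non-maximum suppression is essential under heavy
   noise: a single stay whose scatter exceeds the bandwidth produces a
   constellation of secondary maxima around the true one, and without
   suppression each fragment can accumulate enough visit time to be reported
   as a separate (false-positive) stop. The 250 m floor encodes a judgment
   that two candidate maxima closer than a single site's footprint are one
   place regardless of how small the bandwidth is; its cost is that true
   places closer than the suppression radius cannot be told apart, which is
   the close-stop discrimination trade-off quantified by
   `close_stop_discrimination()`.
3. **Allocation** (`assign_fixes()`): each fix goes to the nearest peak if
   that distance is at most `h`, else to the trip class. Ties within 1 nm
   resolve to the lowest peak id.
4. **Timetable** (`build_visits()`): maximal runs of consecutive fixes with
   one peak label become visits; visits to the same peak separated by at
   most `merge_gap` merge, spanning the gap. The gap tolerance exists
   because at high noise a fix can momentarily leave the allocation radius;
   without merging, those excursions both fragment the visit list and bite
   chunks out of the measured stay. 90 s (nine fix intervals at the default
   sampling) keeps the measured duration of heavily noisy stays within a few
   percent of truth; at 60 s the loss from discarded excursions reaches ~10%
   in the worst noise band.
5. **Stops** (`detect_stops_kd()`): a peak is kept when its summed visit
   time reaches `min_stop_duration` and at least `min_peak_support` fixes
   were allocated to it. Trip streams cannot pass the duration filter at
   plausible speeds: a 10 m/s pass-through occupies a peak's `h`-radius for
   at most `2h/speed` seconds. The reported location is a mean-shift
   refinement: starting from the density maximum, the centroid of allocated
   fixes within `min(h/2, refine_radius)` is iterated to a fixed point. A
   plain centroid of *all* allocated fixes is biased 20–30 m at wide
   bandwidths by the trip fixes that fall inside the allocation radius; the
   windowed iteration removes that drag while keeping sub-cell precision.
   Both alternatives (`location = "peak"`, `"centroid"`) remain available.

### The comparator

`detect_stops_ft()` scans fixes in time order. A cluster grows while the
next fix lies within the roaming radius `d` of the cluster's *first* fix;
on the first violation the cluster is emitted as a stop if its time span
reaches `min_stop_duration`, and a new cluster starts at the breaking fix.
The centroid is the reported location. Testing membership against the
anchor rather than the running centroid is a deliberate reading of this
algorithm family: it reproduces the family's documented failure profile —
fragmentation once noise approaches `d` (duration underestimation, false
positives from long stays splitting) and, at wide radii, clusters anchored
on approach trips that split or absorb stays. The more forgiving
running-centroid variant is available as `centroid_test = TRUE`. No pending
buffer is kept: a single excursion breaks the cluster, and consecutive
emitted stops are never merged afterwards.

## The synthetic benchmark

`generate_track_set()` emulates a controlled study design rather than any
particular city: per track, three stop centres uniform in a 6 km square
(visited in draw order), a dwell duration drawn per stop from one of three
categories — [6, 20] min, [20, 120] min, [2, 6] h, category chosen
uniformly — straight-line trips at a constant 36 km/h, fixes every 10 s,
and isotropic Gaussian noise applied to every fix with a per-axis SD drawn
once per track from U[0, 200] m. Choices the design leaves open were fixed
once, for these reasons:

* **Duration bounds.** The short category starts at 6 min so that every
  simulated stop exceeds the 5-min detection threshold (otherwise "three
  detectable stops per track" would be false by construction), and the open
  top category is capped at 6 h so it can be sampled.
* **Stop placement.** Uniform with no minimum separation; with three stops
  in a 6 km square this yields close neighbours (two stops within 800 m) on
  roughly 12–15% of tracks, enough to exercise the discrimination
  indicator.
* **Noise semantics.** `noise_m` is the per-axis SD of the bivariate
  displacement, drawn per track and applied to stop *and* trip fixes (a
  stops-only variant exists as `noise_stops_only`). The per-track draw makes
  the four noise strata [0,50), [50,100), [100,150), [150,200] m exact
  partitions of the track set.
* **Reproducibility.** One master seed; each track runs on its own
  substream (seeds drawn once from the master stream), so any single track
  can be regenerated without generating the rest.

What the generator does *not* emulate — and therefore what passing this
benchmark does not establish about field data: signal dropouts indoors and
in urban canyons (real traces need gap interpolation before density-based
detection), speed variation and mode changes on trips, autocorrelated or
systematically biased noise (urban multipath shifts positions, it does not
just scatter them), and network-constrained movement. Results on synthetic
tracks bound what the algorithms can do under known noise; they do not
replace validation against prompted-recall ground truth.

## Evaluation conventions

A processed track is *on target* when exactly three stops were detected and
none lies farther than 1 km from every true stop; fewer is a false
negative, more a false positive, and a count-coincidence with a >1 km
detection is discarded as an outlier (the whole track, not the stop).
Spatial and temporal accuracy are computed on on-target tracks only — with
the wrong stop count, detected-to-true correspondence is arbitrary — by
matching each detected stop to its nearest true stop. Matching is
independent per detected stop; a one-to-one assignment (exhaustive over
permutations, fine for three stops) is available and used nowhere by
default. The relative duration error is signed, `(found − true)/true`;
summaries report the signed mean, its SD, and the mean absolute error.
Noise bins are half-open with the last closed at 200 m, so the bins
partition [0, 200].

Two structural identities are worth knowing when reading duration and
location numbers. First, trip fixes within `h` (or `d`) of a place join its
visits, so even noise-free durations overestimate by up to `2h/speed`
seconds — at wide bandwidths this is the dominant temporal error and is why
larger bandwidths overestimate stay time. Second, for the comparator, trip
fixes land every ~100 m at the default speed and sampling, so any radius at
or above that spacing absorbs a short trip tail into each stay's cluster:
locations cannot be exact there, and the tests assert the corresponding
bound instead.

## Numerical choices and degenerate inputs

Grid origin is tied to the fixes' bounding box, so translating a track by a
whole number of cells translates the output exactly (asserted as a test).
An empty fix set is an error for the surface; an all-zero surface yields no
peaks and no stops; a track whose every peak fails the duration filter
yields an empty, correctly-typed stop table. Duplicate timestamps are
dropped (first kept, with a warning) at I/O, not silently tolerated inside
the detectors. Geographic input is projected once at the I/O boundary with
a spherical azimuthal-equidistant projection — chosen over the simpler
equirectangular form because pairwise distances 10 km from the reference
err by ~0.16% at mid-latitudes under the latter, breaching the 0.1%
fidelity the detectors' metric assumptions deserve; fixes beyond 100 km of
the reference are refused.

## Known limits

* **Kernel resolution.** Two equal-mass quartic kernels merge into a single
  maximum when their centres are closer than ≈1.09 h (for unequal masses the
  weaker peak is swallowed even earlier). At `h = 1000 m` every pair of
  stops closer than ~1.1 km collapses, which with uniform placement in a
  6 km square affects roughly a quarter of tracks. This is intrinsic to
  KDE peak extraction, not an implementation artifact; at the widest
  bandwidth the comparator can therefore match or exceed the kernel
  detector on stop counts, while losing heavily on spatial accuracy.
* **Short-stay location floor.** A 6-min stay carries ~37 fixes; at a noise
  SD of 175 m per axis, even the exact centroid of those fixes errs ~36 m
  on average. No estimator can beat that floor from the track alone, which
  bounds achievable spatial accuracy in the highest noise stratum.
* **Suppression vs discrimination.** The 250 m suppression floor trades
  false positives under noise against the ability to separate places closer
  than 250 m; applications tracking within-campus movement should lower it
  along with the bandwidth.

## Problem sizes in the tests

The package's test suite runs the full factorial benchmark once — 750
tracks × 6 bandwidths × 2 algorithms, about three minutes of compute — and
asserts the headline indicators at their stated tolerances, alongside unit
and property tests (oracle equivalence of the surface against brute-force
summation on ≤500-fix instances, mass conservation, translation
equivariance, noiseless parameter recovery at every bandwidth, determinism
of regeneration). `scripts/acceptance.R` reruns the same computation from
scratch at a caller-chosen seed and writes the measured quantities as JSON.
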