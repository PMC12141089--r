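---
title: "Effort-corrected range-shift trends from checklist data: methods"
author: "gridShift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effort-corrected range-shift trends from checklist data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridShift)
```

## The estimation problem

Semi-structured checklist data record where observers went and what they
saw, not where a species is. Between-year changes in the spatial
distribution of observer effort therefore masquerade as range shifts.
This package estimates linear trends in a species' breeding-range
position — centroid latitude/longitude and the four bounding-box limits —
while absorbing effort redistribution through a matched covariate: for
every positional metric computed over *detection* cells, the same metric
is computed over *all sampled* cells and entered into the regression.

The full chain is: zero-fill → filter → equal-area grid → score
cell-years → per-region annual metrics → per-metric OLS with effort
covariate → degree-to-km conversion.

## Presence scoring on an equal-area grid

Checklists are projected with a spherical Albers equal-area conic
(standard parallels 29.5° and 45.5° N, origin 23° N / 96° W, authalic
radius 6 371 007.2 m) and binned into square cells (default 10 km) with
half-open membership `[x, x+s) × [y, y+s)`, making cell assignment a
partition. Equal-area projection matters because presence scoring counts
cells: under a conformal or geographic grid, northern cells would be
smaller and the scored surface biased with latitude. The projection is
implemented in closed form (Snyder's spherical formulas) and verified in
the test suite against the analytic spherical-quadrilateral area and by
round-tripping.

Cells with checklists in fewer than `minYears = 5` distinct years are
dropped. Retention counts *sampled* years, not detection years: the rule
screens sampling consistency, and conditioning it on detections would
bias the scored surface toward occupied cells. The retained cell-by-year
checklist and detection counts form a `CellYearMatrix`
(SummarizedExperiment: assays `checklists`, `detections`; rowData = cell
geometry and region).

Per region and year, the detection centroid is the area-weighted
centroid of the union of detection cells, computed in projected space by
the shoelace formula and transformed to degrees. Because cells partition
the plane, the union centroid equals the mean of cell centres; the test
suite asserts agreement to 1e-9 projected metres, and the per-cell
shoelace is evaluated in cell-local coordinates because at continental
magnitudes the raw formula loses metre-scale precision to cancellation.
Range limits are coordinate extremes over transformed cell *corners*
(edges, not centres). Effort metrics use the same retained cells scored
by presence of any checklist, so the covariate is like-for-like with the
response; an alternative would be raw checklist coordinates, but then
covariate and response would differ in granularity and retention.

## Trend model

For each region–metric pair, with one observation per year (13 by
default),

y_t = b0 + b1 t + b2 e_t + eps_t,

by ordinary least squares; `b1` (deg/yr) is the estimate of interest,
tested two-sided at alpha = 0.05 with no multiple-testing correction
(the battery is 22 tests; raw p-values are reported, as is conventional
for this analysis). Collinearity between year and the effort covariate
is diagnosed by VIF = 1/(1 − r²); fits with VIF ≥ 10 are flagged. Fits
with fewer than 4 complete years return an explicit `INSUFFICIENT`
status rather than an estimate. Range-wide, all six metrics are fitted;
within regions, only the two centroid axes (boundary limits of a
sub-region clip at region borders and are less interpretable).

Cumulative displacement over the study is `b1 × spanYears ×
111.32 km/deg`, with longitudes further scaled by `cos(reference
latitude)`. Defaults: `spanYears = 13`, the inclusive year count of
2010–2022 — the only multiplier consistent with both worked conversions
the package reproduces (0.161 × 13 × 111.32 ≈ 233 km; 0.084 × 13 ×
111.32 ≈ 121.6 km); an interval-count policy (12) can be configured.
The reference latitude is the region's mean detection-centroid latitude
across years (policy `region_mean_centroid_lat`), or a fixed value; a
`noCos` switch disables meridian convergence entirely for exploring
uncorrected longitudinal arithmetic.

## The synthetic observation process

`generateChecklists()` emulates the structural features of an EBD
extract that this analysis is sensitive to, with known ground truth:

- **Effort**: checklist locations are drawn from a Gaussian-mixture
  effort surface (`effortCenters`: lat, lon, weight, sd in km) whose
  centres drift at `effortDrift` deg/yr. The default is a 4 × 4 lattice
  of 150 km-sd clusters over lat 41.5–48° / lon −114…−106°.
- **Occupancy**: detection on a checklist is Bernoulli with probability
  `detectionP0 · exp(−d²/(2·occSdKm²))`, `d` the planar distance to the
  year's kernel centre (default sd 100 km, centre (44.2, −110), drift
  `occDrift` deg/yr, `detectionP0 = 0.6`).
- **Scale**: 3300 checklists/year for 2010–2022 (≈ 43k total, the scale
  of a filtered single-species extract for a wide-ranging western
  grassland shorebird).
- **Contaminants**: incidental-protocol, incomplete, over-distance
  (traveling > 5 km) and over-duration (> 5 h) checklists are injected
  mutually exclusively at configured fractions (5/8/4/3% by default) and
  echoed in a truth record, so the filter exclusion report can be checked
  against the injected counts *exactly* (clean records are generated
  strictly inside every threshold).
- **Counts**: detections get 1 + Poisson(1.2) individuals; 2% are
  recorded as "X" (present, count unknown), which the reader parses as a
  detection with missing count — the analysis is presence-based, so
  counts never enter downstream math.
- **Determinism**: one substream seed per simulated year is derived from
  the master seed, so extending the year span reproduces the shared
  years bit-for-bit.

Distances are computed on the equal-area projected plane rather than
geodesically; at the simulated extent the approximation error is far
below the kernel scale.

### Why these defaults

The effort lattice and kernel size were calibrated together, against the
estimator's own diagnostics, before the acceptance checks were frozen.
Two failure modes constrain them from opposite sides:

- *Attenuation.* The detected-cell-set centroid is effectively a
  detection-probability-weighted average over the effort surface. If the
  effort density has strong gradients across the occupancy kernel, the
  centroid is pulled toward static effort mass and an imposed drift is
  recovered shrunken (roughly by σ_e²/(σ_e² + σ_k²) for Gaussian effort
  of scale σ_e and kernel σ_k). A first-draft layout of scattered city
  clusters with a 300 km kernel attenuated a 0.1 deg/yr drift to
  ~0.03 deg/yr. Near-uniform coverage across the kernel's whole
  trajectory removes the bias.
- *Retention starvation.* At 3300 checklists/year, spreading effort too
  thinly leaves per-cell sampling rates so low that the ≥ 5-year rule
  retains almost nothing and the annual centroid becomes noisy. The
  well-sampled window is therefore kept compact (~900 × 950 km) and the
  kernel compact (100 km sd) with its 13-year trajectory, ±2.5 sd,
  inside the window.

With these defaults the estimator recovers an imposed 0.1 deg/yr
northward drift with mean slope ≈ 0.095 and model SE ≈ 0.01, and its
type-I error under no drift is calibrated (the acceptance suite measures
both).

The default layout is deliberately *confound-free*: static uniform
effort cannot bias the trend, which is the right baseline for parameter
recovery and null calibration. To study the effort confound itself the
package ships `confoundEffortCenters()` — a single 150 km cluster
centred 1.2° south of the kernel. When that cluster drifts north at
0.2 deg/yr over a stationary species, the uncorrected regression reports
a spurious northward slope (≈ +0.06 deg/yr), and adding the effort
covariate shrinks it substantially (the acceptance suite quantifies the
reduction over 200 replicates).

What the generator does **not** emulate: residual spatial
autocorrelation of effort within clusters, observer heterogeneity in
detection skill, misidentification, range shape beyond a single Gaussian
kernel, or list-level covariance between effort variables and detection.
Passing tests therefore demonstrate correctness of the pipeline's
bookkeeping, geometry and estimator under a clean generative model —
not robustness to every pathology of real community-science data.

## Regions

Region polygons (e.g. Bird Conservation Region boundaries) are read from
GeoJSON; a cell belongs to the region containing its centre point
(deterministic, order-tie-broken at shared edges), and the union of all
regions is the implicit `full_range` region. Synthetic stand-in fixtures
(`makeRegionFixture()`): two rectangles, or eight longitudinal bands
mimicking an eight-region stratification. Membership by centre rather
than overlap fraction trades boundary-cell precision for determinism and
speed; at 10 km cells against region-scale polygons the difference is a
one-cell ribbon.

## Numerical and policy choices

- Thresholds keep boundary values (exactly 5 km / 5 h pass): exclusion
  is stated as strictly "longer than".
- Records with missing duration are excluded (effort unquantifiable);
  missing distance excludes only traveling checklists.
- Exclusions are attributed to the *first* failing rule in the fixed
  order protocol → completeness → distance → duration → season → year;
  membership of the kept set is order-independent.
- Shared (group) checklists are collapsed to one representative (lowest
  checklist id; detection OR over the group) to avoid pseudo-replication;
  a `strictPaper` switch disables this for strict replication of
  pipelines that skip it.
- "X" counts are detections with unknown count.
- Geographic outputs are rounded only at write time (6 decimals); all
  arithmetic is double precision.
- Empty cell sets (a region-year with no detections) yield explicit NA
  metrics and are dropped pairwise by the regression.

## Problem sizes

The shipped test suite runs the full pipeline at the default scale
(3300 checklists × 13 years) across 100 seeds for drift recovery, 200
for null calibration, and 200 for confound mitigation; bookkeeping
checks use 10,000 records and the geometric oracles 500 random cell
sets. These sizes give the binomial bands and Monte-Carlo tolerances
used in the assertions.

## Limitations

Presence scoring ignores detection probability; a cell-year with many
checklists is more likely to score a detection, which is why the effort
covariate and the retention rule exist, but a hierarchical occupancy
model would treat this directly. OLS on 13 annual points has limited
power and assumes independent errors across years. Bounding-box limits
are extreme-value statistics and noisier than centroids. Longitude-to-km
conversion uses a single reference latitude per region.
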