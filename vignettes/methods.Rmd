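---
title: "Canopy height from point clouds, echoes and surface models: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy height from point clouds, echoes and surface models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyscan)
```

This vignette is the package's own account of its science: the processing
models, the assumptions they rest on, the tunable parameters and why their
defaults are what they are, what the synthetic data generator does and does
not emulate, and the numerical choices a maintainer would otherwise have to
reverse-engineer.

## 1. The measurement problem

Plot height in a wheat breeding trial is the height a person measures with
a yardstick: soil surface to the top of the stem during vegetative stages
(method A), soil surface to the top of the spike, excluding awns, once
plants head (method B). Sensors do not observe that quantity directly. A
LiDAR sees a cloud of returns from every canopy layer and the soil; an
ultrasonic rangefinder sees one echo from whatever surface reflects enough
sound; a photogrammetric surface model sees the topmost texture a camera
can resolve. The package's common abstraction is the **percentile ladder**:
per plot, the ordered heights at a fixed grid of cumulative percentiles of
whatever height distribution the sensor produced. Which rung best predicts
the manual height is an empirical question answered by the evaluation layer
per method category.

Percentiles use linear interpolation between adjacent order statistics
(the type-7 convention, the common default of scientific software) on the
grid `step, 2*step, ..., 100`. Excluding the 0% endpoint makes the 0.5%
LiDAR grid exactly 200 rungs and the 1% pixel grid exactly 100 — the only
uniform grid consistent with both counts. The generator records, per plot,
the continuous percentile at which the true height sits in the generated
height set (the inverse of the same interpolation), which makes percentile
recovery exactly testable.

## 2. LiDAR chain

### Frames and windowing

Polar records decode by the spinning-scanner convention
(`x = r cos ω sin α`, `y = r cos ω cos α`, `z = r sin ω`); a rigid mounting
transform (default: spin axis onto the travel axis, so the fan sweeps
across the plots and downward) produces the cart frame — origin at the
sensor optical center, X across plots, Y along travel, Z up. Clouds are
trimmed to the closed window `|x| <= 1.5 w` and split at `±0.5 w`, border
points going to the middle plot; both boundary conventions are fixed
choices where the field protocol is silent, made closed/middle-inclusive
for determinism.

### Tilt correction

The cart tilts on uneven ground, so the scene appears rotated in the
sensor frame. One correction pass fits ordinary least squares to the X–Y,
X–Z and Y–Z projections in turn and counter-rotates about the orthogonal
axis by `atan(slope)` after each fit (about Z, then Y, then X, about the
cloud origin so sensor-height semantics survive). Because finite rotations
about different axes do not commute, passes repeat until all three refit
slopes fall below `tolerance` (default 1e-6, at most `max_iterations = 10`
passes; non-convergence returns the cloud with a warning flag). The
recovered roll/pitch/yaw are reported by Euler decomposition (Rz·Ry·Rx
convention, matching the generator's pose composition) of the accumulated
correction — per-pass angle sums do not compose into Euler angles beyond
first order, a 0.5–1.5 degree effect at 10-degree poses.

Two properties of this estimator matter for interpretation:

* **It fits all points, not segmented ground.** That is valid exactly when
  the canopy surface parallels the ground, i.e. when the three plots in a
  scan have comparable heights. A real height gradient across the scan is
  observationally identical to roll; the package leaves it in (the field
  method has the same confound) and the synthetic study absorbs it into
  LiDAR's error budget.
* **The trim window interacts with tilt.** Trimming in the tilted frame
  clips edge points selectively by height, biasing the fits by up to
  ~0.5 degrees at 10-degree poses. Pose-recovery analyses therefore apply
  a non-binding window (the simulated scan contains only the three target
  plots); the study pipeline keeps the standard window, bias included.

### Ground baseline

Default `histogram_peak`: the ground level is the mean Z inside the
maximal-count 0.01 m bin over the cloud's lower half-range. Taking the
in-bin mean rather than the bin center costs nothing and removes the
±5 mm quantization, making the degenerate flat-ground case exact. With
fewer than 50 points below the median the histogram is unsupported and
the measured sensor height takes over (with a warning). `sensor_height`
and `fixed` strategies are available directly; heights in a corrected,
re-based cloud are then `Z - ground_z`, ground returns clustering at 0.

## 3. Ultrasonic chain

The lab calibration `D = 29.116 V + 11.641` is implemented exactly as
printed, with a configurable `unit_scale` for the output unit. Taken as
meters, 10 V would map to 302.8 m from a sensor specified to 4.27 m; read
as centimeters the full 0–10 V range spans 0.12–3.03 m, which is
physically coherent. The package therefore defaults to `unit_scale = 0.01`
and keeps the as-printed meters reading selectable — the ambiguity is
documented rather than silently corrected. Canopy height is
`H_c = H_s - D·unit_scale`; negative values (tilted cart, soil path longer
than the measured sensor height) are flagged, never clamped.

## 4. UAS chain

The DTM is interpolated from a random ~40% subset of the DSM's soil
pixels by ordinary kriging: exponential variogram
`γ(h) = nugget + psill (1 - exp(-h/range))` fitted to the binned empirical
semivariance by least squares (15 bins to half the maximum separation),
nugget floored at 1e-6 so the system stays well conditioned while the
semivariance matrix keeps zeros on its diagonal — which is what makes the
predictor honor every sample exactly. Inverse-distance weighting (power 2)
is the fallback for degenerate sample geometry. Two tractability
parameters, both with exactness preserved where it is tested:

* `max_points` (default 500) caps the kriging system; beyond it samples
  are thinned deterministically. A full system on tens of thousands of
  soil pixels would be O(n³).
* `stride` (default 1) evaluates the surface on a strided lattice and
  bilinearly resamples, overwriting sampled cells with their exact
  elevations. The study uses stride 4; the terrain model is smooth at
  that scale and the resampling error is far below the sensor noise.

The height map is the cellwise difference of congruent grids; nodata
propagates and negative cells are preserved (percentile selection is
robust to a negative tail). Zonal extraction uses the cell-center rule —
the standard zonal-statistics convention.

Because the DTM is kriged from the *same* DSM, smooth mosaic-scale error
cancels in DSM − DTM. This is a real property of the
soil-segmentation approach and is why plot-level UAS error is driven by
what the camera cannot see, not by georeferencing drift.

## 5. What the generator emulates, and what it does not

A scene is a grid of plots (default 10 × 10, plot width 1.524 m, plot
length 2.4 m, 0.6 m alleys, vegetated width 1.2 m) on a planar sloped
terrain with Gaussian micro-relief, each plot carrying a true height.
Within-plot canopy heights follow a normal with mean `0.85 h` and sd
`0.08 h`, truncated to `[0, 1.05 h]`: the thin upper tail puts the true
height near — but below — the 100th percentile, as leaf-top distributions
do in the field. Ground returns are 30% of a scan's points (a stand-in;
the field fraction is unreported and varies with cover). Canopy cover
defaults to 85%.

Sensor error budgets are set to the magnitudes the field-phenotyping
literature reports per modality, chosen once: LiDAR ranging noise 5 mm;
DSM cell noise 2 cm correlated over 0.25 m patches plus a smooth 4 cm
mosaic error field over ~3 m (dense-matching error is locally correlated —
iid pixel noise would let a 100th percentile harvest its own upper tail);
manual references average three replicates of 2 cm noise. The
photogrammetric surface resolves only a fraction of the true height once
spikes emerge (cameras cannot see thin spikes): per-campaign visible
fractions default to 1, 1, 0.93, 0.91, 0.89, derived from the reported
near-zero vegetative bias and ~7 cm reproductive underestimation of
UAS height maps. The ultrasonic echo returns from the
`echo_depth_percentile` of the canopy inside a 7-degree half-angle cone —
from the top for young, leafy canopies (default 100 at the first
campaign), from progressively deeper as sparse spikes stop reflecting
(60, 40, 30, 25) — with 5 cm echo noise; an empty footprint echoes from
the soil.

Two constructions make ground truth exactly recoverable rather than
recoverable-in-expectation. Per-plot uniform draws are recentred (and
minimally rescaled within their design rectangles) to their design means,
and the noise components are orthogonalized against the plot coordinates,
so an untilted scan has exactly zero least-squares slopes — pooled and on
the ground subset. The applied pose is then exactly identifiable by the
correction, and what remains confounded with tilt is only real structure
(terrain slope, cross-plot height differences). Without this, a sampling
covariance of order `sd/sqrt(n)` — about 0.2–0.5 degrees at scan densities
— would be an irreducible floor under every recovery test.

Not emulated: beam-level ray casting and multi-return echoes (the pipeline
consumes Cartesian clouds; occlusion does not change any tested contract),
radiometry, wind deformation (reported as a major scatter source late in
the season, but no usable model accompanies the observation), temperature
dependence of the speed of sound, and automatic soil segmentation (the
soil mask is an explicit input). Passing tests therefore demonstrate the
pipeline's correctness and its behavior under the modeled error structure
— not robustness to wind-deformed clouds or segmentation errors.

## 6. The synthetic study

`run_simulation_study()` measures 100 plots in five campaigns (methods
A, A, B, B, B), plot heights growing as 0.35, 0.55, 0.75, 0.90, 1.00 of a
per-plot potential drawn from 0.7–1.1 m — mature wheat stature, with the
plot-to-plot spread of a breeding trial. Each field row of ten plots is
covered by static scans centered on plots 2, 5 and 8 plus a remainder
scan, giving 30 middle and 70 side plots per campaign (the field design
that motivates the side/middle stratification). Scan poses draw
roll/pitch/yaw from N(0, 3°) clamped to ±10°. Per campaign the DSM is
generated at 5 cm GSD (~183k cells), 40% of soil pixels sampled, DTM
kriged with 500 system points at stride 4. These problem sizes keep a
full study around 20 seconds on one core while preserving the point
densities (~6000/~8000 per side/middle plot) and grid resolutions that
the extraction contracts are written against.

Every stage derives its stream from the master seed; identical
(config, seed) reproduce the study bit for bit, and the report carries
raw-vs-processed, category/position and sensor-comparison tables.

## 7. Numerical choices and degenerate inputs

* Rounding of printed derived statistics: half away from zero, 2 decimals
  for percentages, 4 for meters — matching how such tables are typeset.
* Ties in the optimal-percentile argmin break toward the lowest
  percentile; the R²-optimal percentile is reported alongside because the
  two optima genuinely disagree for vegetative campaigns.
* R² is the squared Pearson correlation, reported next to a separate
  bias; the `1 - SSres/SStot` identity-line convention is selectable.
  (A correlation convention is the only one consistent with reporting
  high R² together with substantial systematic underestimation.)
* Degenerate inputs error early and by name: empty height sets, rasters
  that do not overlap a polygon, non-congruent grids, non-rigid mounts,
  collinear kriging geometries (which fall back to IDW with a warning),
  constant vectors in correlations (reported as NA in assembled reports).
* Azimuth windows are half-open `[lo, hi)` to avoid double-counting the
  seam; trim windows are closed; split borders belong to the middle plot.

## 8. Known limitations

The tilt estimator inherits the canopy-structure confound discussed above;
on strongly height-heterogeneous neighborhoods its correction can be worse
than no correction, which is visible in the simulator when plot heights
are drawn from an implausibly wide range. The kriging variogram fit is a
least-squares point estimate with no uncertainty propagation. The
ultrasonic model reduces a transducer's beam physics to one percentile
of a cone — adequate for studying the estimator chain, not for sensor
design. The study's reported sensor ranking reflects the modeled error
budgets; it is a property of the simulation conditions, not a field
measurement.
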