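---
title: "Modelling road-traffic noise with land-use regression: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling road-traffic noise with land-use regression: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lurnoise)
```

## The problem

Strategic noise maps of the day–evening–night indicator Lden exist only
where regulation requires them: large agglomerations and major roads. The
surrounding, unmapped communities are exactly where epidemiologists most
need exposure estimates. Land-use regression (LUR) offers a scalable
answer: treat the cells of an existing engineering-grade noise map as
*virtual microphones*, learn a statistical relationship between Lden and
publicly available geodata (roads, buildings, terrain, land cover), and
deploy that model beyond the mapped boundary.

`lurnoise` implements this pipeline end to end on a 10-m analysis grid:
predictor engineering, virtual-microphone sampling under four schemes,
ordinary-least-squares model fitting, conventional and spatially blocked
cross-validation, and area-wide prediction with residual and threshold
reporting. Because the reference inputs of a real study are licensed and
location-bound, the package ships a first-class synthetic-scene module, so
every stage is reproducible and testable from a seed.

## The model

The response is Lden in dB(A) at cell centres. The predictor space is:

* **Log-proximity per road type** — for each of the six OSM-style
  functional classes (motorway, trunk, primary, secondary, tertiary,
  residential), the Euclidean distance d (m) to the nearest non-tunnel
  segment, transformed as `log10(d + 1)`. Sound decays approximately
  linearly in log distance; the +1 m offset makes the on-road value
  exactly 0. Functional class proxies traffic volume and speed when
  counts are unavailable; tunnels are excluded throughout.
* **Lane-weighted cumulated road length** — per type, each cell holds the
  exact clipped in-cell length times the lane count (lane weighting is the
  standard emission proxy of the European good-practice guidance); a
  circular focal sum within a radius, reported in km, captures
  accumulated exposure from intersections and parallel carriageways.
* **Topographic position indices** — for both the DEM and the
  building-height model, TPI = centre value minus the neighbourhood mean
  (centre excluded). Positive values mark locations superior to their
  surroundings, negative values valleys and courtyards — the volume
  available for propagation.
* **Land-cover fractions** — percent of each of seven classes (artificial,
  open soil, high/low × seasonal/perennial vegetation, water) within the
  window, encoding ground absorption and reflection.

Windowed variables are computed at eight systematically scaled radii
(12.5, 25, 50, 100, 200, 400, 800, 1600 m), log-like spacing mirroring the
logarithmic attenuation of sound: 6 proximity + (6 + 1 + 1 + 7) × 8 = 126
candidate columns. An a-priori univariate screen then fixes one radius per
windowed variable: at each radius an intercept-and-slope OLS of sampled
Lden on the variable is fitted and the radius with the smallest in-sample
RMSE is kept (ties break to the smaller radius), leaving 6 + 15 = 21
predictors. The screen is deliberately univariate and performed once —
multivariate or per-campaign selection would confound the sampling
experiments the package exists to study.

The model itself is OLS with classical standard errors; transferability is
judged by cross-validation rather than by robust inference. Predictions
are never clipped: deployment beyond the training range is an intended
use, and extrapolated values are informative.

## Sampling designs and their evaluation

`draw_sample()` implements four campaign designs over the valid cells:
uniform **random**; **systematic** on a square lattice with spacing
`sqrt(valid_area / N)` (the seed sets the lattice offset within one
spacing; if the lattice lands on more than N valid cells a seeded
subsample trims to N, keeping `N_sampled <= N` by construction);
**stratified by 5-dB Lden bins** (left-closed, anchored at 0 dB(A)); and
**stratified by settlement-structure zones**. Stratified schemes use equal
allocation — `floor(N/K)` per non-empty stratum, remainder to the largest
strata — because the design intent is to represent rare loud conditions,
which proportional allocation would reduce back to random sampling.
Scarce strata contribute all their cells, so the realised `N_sampled` can
fall below the request; that shortfall is reported, never hidden.

Each campaign is checked for representativity with a pooled-variance
two-sided t-test of the sample against the full valid-cell population.
Cross-validation comes in four flavours: leave-one-out (LOOCV), repeated
leave-group-out (LGOCV at a held-out fraction; default 20 repeats — the
repeat count is a free parameter and configurable), and two
leave-structure-out variants blocked by admin districts or by
settlement-structure classes (LSOCV). The spatially blocked variants are
the harsher and more honest test when samples are spatially
autocorrelated: each fold forces extrapolation into an unseen area. A
model counts as robust when overall R² minus cross-validated R² stays
strictly below 0.15.

`run_campaign_grid()` executes the full scheme × size × seed design
independently per cell of the grid (the reference design is 4 × 5 × 100 =
2000 campaigns; seeds are the integers 1..S), records failures explicitly,
and `aggregate_results()` summarises accuracy into mean, sd and the 5/95
percentiles using linear-interpolation quantiles (the default type-7 rule,
stated here because percentile conventions differ).

## The synthetic scene and acoustic fixture

`generate_scene()` builds a river-valley study area: a DEM composed of a
valley gradient plus smoothed Gaussian relief, a hierarchical road network
touching all six types (motorway and trunk as through-routes — the trunk
carries a short tunnel — primaries along the river, secondary/tertiary
connectors, residential street grids in three settlement blocks),
building clusters along residential streets, a seven-class land-cover
mosaic with every class guaranteed present, nine admin districts and six
settlement-structure zones. All randomness flows through one integer seed;
the same seed reproduces the scene bit for bit.

`simulate_lden()` provides the reference map by energetic summation:
non-tunnel segments are discretised into point sources every 10 m, each
radiating its type's emission level anchored at published per-type on-road
means (83.90, 76.37, 73.14, 68.00, 60.13, 51.44 dB(A) from motorway down
to residential — see `road_lden_reference()`), with

* log-distance spreading (20 dB/decade, spherical point-source default),
* a ground term of 10 dB/km applied when the receiver cell is vegetated —
  a deliberate simplification of path-integrated ground absorption that
  keeps the computation closed-form while leaving a land-cover signal the
  LUR can recover,
* an elevation term (0.05 dB per metre the receiver sits above the
  source), so valley locations are louder, as a terrain TPI should detect,
* an optional fixed building-shielding penalty behind built cells, off by
  default (`shielding_db = 0`) because its sampled line-of-sight test is
  intended for small diagnostic scenes, not the campaign fixture.

This is fixture physics, not an engineering calculation: no reflections,
meteorology or diffraction. What passing tests on it demonstrate is that
the *pipeline* recovers structure it is pointed at — proximity gradients,
density, terrain and land-cover effects — not that the model would reach
any particular accuracy on a real city. The second fixture,
`generate_linear_lden()`, goes further and makes the truth exactly linear
with known coefficients, so OLS recovery can be verified to numerical
precision (noise-free) and to within classical standard errors
(noise-added).

## Numerical choices

* **Focal windows** are circular by centre-to-centre distance (radii are
  what the method speaks in; square windows were rejected), computed by
  FFT convolution with zero padding. Means normalise by the number of
  available in-domain cells, so edges average over what exists; sums are
  left edge-truncated. Window counts are rounded back to integers to
  remove FFT noise.
* **TPI** excludes the centre cell from the neighbourhood mean (on a flat
  surface the choice is invisible; on a peak it changes the value by a
  known factor — the excluded-centre form keeps "positive = superior"
  exact). Cells with no in-window neighbour get 0.
* **Rasterization** of road length cuts each polyline edge at every grid
  line and assigns pieces by midpoint, conserving total lane-weighted
  length to 1e-6 relative; zone membership is by cell centre with strict
  half-open edge rules, so partitions are unambiguous and overlapping
  zone polygons are rejected.
* **Degenerate inputs**: zero-variance predictor columns (e.g. no motorway
  sampled at N = 50) are dropped with a warning rather than aborting a
  campaign; rank-deficient designs are an error naming the collinear
  columns; CV folds whose training side is smaller than the coefficient
  count are skipped with a logged reason; a zero-variance t-test
  degenerates to p = 1 (equal means) or p = 0.
* **Thresholds** use strict "below" (a cell at exactly 55 dB(A) is not
  below 55); residual bins are 5-dB, left-closed, anchored at 0.

## Problem sizes used in the checks

The shipped test-bed runs a deliberately scaled-down version of the
reference design: a 300 × 300-cell (3 × 3 km) acoustic scene, campaign
grids of 4 schemes × {50, 200, 1000} × 20 seeds, parameter recovery on a
10,000-cell scene with 100 replicates, and oracle comparisons on instances
of at most 50 × 50 cells. These sizes were chosen so the full pipeline
exercises every code path at desk scale; the qualitative patterns (spread
shrinking with N, stratified oversampling of loud cells, spatial blocking
as the harsher CV) are scale-stable, while absolute accuracy values are
properties of the fixture, not findings about any real city.

## Known limitations

* The acoustic fixture's ground and elevation terms act at the receiver,
  not along the path; street-canyon and backyard effects only appear if
  the optional shielding term is enabled.
* Planar metric coordinates are assumed throughout; reprojection is the
  user's responsibility before data enter the package.
* Only polygonal (admin / settlement-class) blocking is implemented for
  spatial CV; rectangular, hexagonal or radial blocking and buffered-LOO
  variants are out of scope.
* The univariate radius screen inherits the known weakness of marginal
  feature selection under collinearity: with strongly correlated
  candidate columns the chosen radius can reflect shared large-scale
  structure rather than local physics.
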