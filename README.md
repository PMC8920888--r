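# lurnoise

Land-use-regression (LUR) mapping of road-traffic noise (Lden) with
virtual-microphone sampling campaigns, spatially blocked cross-validation
and area-wide prediction.

## The problem

European strategic noise maps stop at regulatory boundaries: road-traffic
Lden is only mapped for large agglomerations and major roads, leaving the
surrounding communities — often the ones of epidemiological interest —
blank. Where an engineering-grade noise map exists, its cells can be
treated as *virtual microphones*: sample them, regress Lden on geodata
that is available everywhere (roads, buildings, terrain, land cover), and
deploy the fitted model beyond the mapped boundary. `lurnoise` is for
exposure modellers and spatial statisticians who want that pipeline — and
the sampling-design and cross-validation experiments around it —
reproducible from a single seed.

## The model

On a 10-m grid, Lden (dB(A)) is modelled by ordinary least squares

```
Lden(s) = b0 + Σ_t b_t · log10(d_t(s) + 1) + Σ_j c_j · x_j(s; r_j) + e(s)
```

where `d_t` is the distance to the nearest non-tunnel road of functional
type `t` (motorway, trunk, primary, secondary, tertiary, residential) and
the `x_j` are moving-window (focal) predictors: lane-weighted cumulated
road length per type (km), topographic position indices (TPI = centre
minus neighbourhood mean) of the DEM and of building heights, and
land-cover class fractions (%). Each windowed variable is computed at the
eight systematically scaled radii 12.5–1600 m; a univariate screen keeps
the radius with the smallest bivariate RMSE, reducing 126 candidate
columns to 21 predictors. Virtual-microphone campaigns vary sampling
scheme (random, systematic lattice, stratified by 5-dB noise bins,
stratified by settlement structure), size and seed; models are evaluated
with LOOCV, repeated leave-group-out CV and two leave-structure-out CVs
blocked by admin districts or settlement classes, with the strict
`R²_overall − R²_CV < 0.15` robustness rule.

Everything runs on synthetic scenes: `generate_scene()` builds a river
valley with a full road hierarchy, buildings, land cover and zones;
`simulate_lden()` produces a reference map by energetic summation of
per-road-type point sources (emission levels anchored at published
per-type on-road means); `generate_linear_lden()` provides an exactly
linear ground truth for parameter-recovery checks.

## Worked example

```r
library(lurnoise)

scene <- generate_scene(seed = 1, n_rows = 150, n_cols = 150)
lden  <- simulate_lden(scene)                      # reference map, dB(A)
stack <- build_feature_stack(scene)                # 126 candidate columns
sel   <- select_radii(stack, draw_sample(lden, "stratified_lden", 500,
                                         seed = 42, strata = lden_strata(lden)))
smp   <- draw_sample(lden, "stratified_lden", 500, seed = 7,
                     strata = lden_strata(lden))   # the field campaign
fit   <- fit_ols(design_matrix(sel$stack, smp$cell), smp$lden)
glance(fit)
#> # A tibble: 1 × 6
#>      r2 adj_r2  rmse   mae     n     p
#> 1 0.958  0.956  2.83  2.08   448    21
head(tidy(fit), 4)
#>   term          estimate std_error statistic   p_value
#> 1 (Intercept)     102.      16.0        6.37 4.92e- 10
#> 2 motorway_prox   -13.0      0.308    -42.2  3.13e-154
#> 3 trunk_prox       -6.94     0.396    -17.5  3.43e- 52
#> 4 primary_prox     -6.50     0.588    -11.1  3.67e- 25
```

The campaign requested 500 microphones but realised 448: scarce loud
strata contribute all their cells (`N_sampled < N`). The in-sample fit
explains 95.8% of the fixture's Lden variance with a 2.08-dB(A) MAE, and
the negative proximity coefficients order like the emission hierarchy
(louder road types pull harder with distance). Transferability and
deployment:

```r
cv <- run_cv(smp, sel$stack, "loocv")
glance(cv)$r2                                   # 0.952
robustness_check(glance(fit)$r2, glance(cv)$r2) # TRUE: drop < 0.15
pred <- predict_raster(fit, sel$stack)
threshold_report(pred, scene$building_height, 55)
#> <threshold_report> 55 dB(A): 19.6% of area below, 0.0% of built-up below
```

On this dense synthetic valley only 19.6% of the area is below the 55
dB(A) strategic threshold, and none of the built-up cells — buildings in
the fixture cluster along residential streets. `autoplot()` methods
render rasters, coefficient plots and campaign-summary curves;
`run_campaign_grid()` / `aggregate_results()` drive the full scheme ×
size × seed experiment. A command-line wrapper over the same functions
ships in `inst/cli/lurnoise` (subcommands `simulate-scene`,
`build-features`, `select-radii`, `sample`, `fit`, `crossval`,
`campaign`, `aggregate`, `predict`, `report`).

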