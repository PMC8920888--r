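#' Reference on-road Lden summary by road type
#'
#' Published summary statistics of simulated road-traffic Lden measured on
#' the road itself (0 m distance) for the six OSM functional road types in
#' a mid-sized German city's strategic noise map. The per-type means anchor
#' the emission hierarchy of the synthetic acoustic fixture
#' (motorway > trunk > primary > secondary > tertiary > residential) and
#' serve as calibration reference values in plausibility checks.
#'
#' @return A tibble with columns `road_type`, `min`, `q1`, `median`, `mean`,
#'   `sd`, `q3`, `max` (all dB(A)).
#' @export
road_lden_reference <- function() {
  tibble::tibble(
    road_type = factor(road_type_levels(), levels = road_type_levels()),
    min    = c(66.90, 55.40, 57.30, 10.50, 18.60, 22.60),
    q1     = c(82.90, 73.50, 70.20, 66.50, 48.60, 46.20),
    median = c(85.90, 77.40, 73.10, 70.00, 67.20, 50.40),
    mean   = c(83.90, 76.37, 73.14, 68.00, 60.13, 51.44),
    sd     = c(4.93, 5.16, 3.68, 7.92, 14.10, 8.39),
    q3     = c(86.90, 79.40, 75.70, 72.20, 70.80, 55.30),
    max    = c(89.10, 86.30, 83.50, 88.90, 84.20, 84.20)
  )
}

#' Reference LUR proximity coefficients by road type
#'
#' Published log-proximity coefficient estimates (dB(A) per log10-metre)
#' from the same study's final LUR model, one per road type. Their strong
#' negative correlation with the per-type on-road mean levels of
#' [road_lden_reference()] (r close to -0.87) is the standard plausibility
#' check that the typed proximity terms encode the emission hierarchy.
#'
#' @return A tibble with columns `road_type`, `beta`.
#' @export
proximity_beta_reference <- function() {
  tibble::tibble(
    road_type = factor(road_type_levels(), levels = road_type_levels()),
    beta = c(-11.93, -8.81, -2.43, -0.56, -0.81, 0.95)
  )
}
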