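#' Acoustic fixture parameters
#'
#' Parameters of the synthetic noise engine that stands in for an
#' engineering-grade strategic noise map. Road segments are decomposed into
#' point sources every `source_spacing` metres; each source radiates its
#' road type's emission level (anchored at the published per-type on-road
#' means, see [road_lden_reference()]), attenuated by log-distance
#' spreading, a ground term over vegetated receivers, an optional penalty
#' for receivers elevated above the source, and an optional fixed building-
#' shielding penalty; contributions combine energetically.
#'
#' @param emission_by_type Named dB(A) emission per road type at reference
#'   distance `d0`. Must respect the emission hierarchy motorway > trunk >
#'   primary > secondary > tertiary > residential.
#' @param d0 Reference distance in metres (>= 1).
#' @param spreading_coefficient dB lost per decade of distance (20 =
#'   spherical spreading of a point source).
#' @param ground_absorption dB per km of propagation towards a vegetated
#'   receiver cell (small positive).
#' @param elevation_penalty dB per metre a receiver sits above the source
#'   (terrain exposure; valley receivers are penalised less, creating the
#'   terrain signal a DEM TPI can recover).
#' @param shielding_db Fixed penalty (dB) when the straight source-receiver
#'   path crosses a built cell; 0 disables the line-of-sight test (the
#'   default - the test is meant for small diagnostic scenes).
#' @param source_spacing Segment discretisation step in metres.
#' @return A list of class `acoustic_params`.
#' @export
acoustic_params <- function(emission_by_type = NULL, d0 = 1,
                            spreading_coefficient = 20, ground_absorption = 10,
                            elevation_penalty = 0.05, shielding_db = 0,
                            source_spacing = 10) {
  if (is.null(emission_by_type)) {
    ref <- road_lden_reference()
    emission_by_type <- stats::setNames(ref$mean, as.character(ref$road_type))
  }
  stopifnot(all(road_type_levels() %in% names(emission_by_type)),
            d0 >= 1, source_spacing > 0, spreading_coefficient > 0,
            ground_absorption >= 0, elevation_penalty >= 0, shielding_db >= 0)
  e <- emission_by_type[road_type_levels()]
  if (any(diff(e) >= 0))
    stop("emission_by_type must decrease from motorway to residential",
         call. = FALSE)
  structure(list(emission_by_type = e, d0 = d0,
                 spreading_coefficient = spreading_coefficient,
                 ground_absorption = ground_absorption,
                 elevation_penalty = elevation_penalty,
                 shielding_db = shielding_db, source_spacing = source_spacing),
            class = "acoustic_params")
}

#' Energetic (dB) summation
#'
#' Combines sound pressure levels energetically:
#' `10 * log10(sum(10^(L/10)))`. Doubling a source raises the total by
#' about 3.01 dB; the total is never below the loudest contribution.
#'
#' @param levels Numeric vector of levels in dB.
#' @export
energetic_sum <- function(levels) 10 * log10(sum(10^(levels / 10)))

# decompose the non-tunnel network into point sources
road_point_sources <- function(roads, spacing) {
  out <- list()
  for (k in which(!roads$tunnel)) {
    g <- roads$geometry[[k]]
    ty <- as.character(roads$road_type[k])
    for (e in seq_len(nrow(g) - 1L)) {
      p1 <- g[e, ]; p2 <- g[e + 1L, ]
      len <- sqrt(sum((p2 - p1)^2))
      if (len == 0) next
      tpos <- if (len >= spacing / 2) seq(spacing / 2, len, by = spacing)
              else len / 2  # short stubs collapse to one midpoint source
      out[[length(out) + 1L]] <- cbind(
        x = p1[1] + tpos / len * (p2[1] - p1[1]),
        y = p1[2] + tpos / len * (p2[2] - p1[2]),
        type = match(ty, road_type_levels())
      )
    }
  }
  if (!length(out)) return(matrix(numeric(0), 0, 3,
                                  dimnames = list(NULL, c("x", "y", "type"))))
  do.call(rbind, out)
}

#' Simulate a reference Lden raster (acoustic fixture)
#'
#' Produces the scene's reference noise surface by energetic summation of
#' per-road-type point sources: each source contributes
#' `L_i = emission + 10*log10(spacing) - spreading * log10(max(d, d0)/d0)`
#' minus the ground, elevation and (optional) shielding penalties, and the
#' per-cell total is `10*log10(sum(10^(L_i/10)))`. Proximity, road density,
#' terrain position and land cover all leave recoverable traces in the
#' result, which is what the LUR predictors are designed to pick up.
#'
#' @param scene A [generate_scene()] result.
#' @param params An [acoustic_params()] list.
#' @return A [noise_raster] in dB(A).
#' @export
simulate_lden <- function(scene, params = acoustic_params()) {
  stopifnot(inherits(scene, "noise_scene"), inherits(params, "acoustic_params"))
  grid <- scene$dem
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cc <- cell_centers(grid)
  px <- rep(cc$x, each = nr)
  py <- rep(cc$y, times = nc)
  veg <- as.vector(scene$landcover$values %in% 3:6) * 1
  elev_r <- as.vector(scene$dem$values)
  src <- road_point_sources(scene$roads, params$source_spacing)
  if (!nrow(src)) stop("scene has no emitting road segments", call. = FALSE)
  s_col <- pmin(pmax(floor((src[, "x"] - grid$origin_x) / grid$cell_size) + 1L, 1L), nc)
  s_row <- pmin(pmax(floor((grid$origin_y - src[, "y"]) / grid$cell_size) + 1L, 1L), nr)
  elev_s <- scene$dem$values[cbind(s_row, s_col)]
  base_db <- params$emission_by_type[src[, "type"]] +
    10 * log10(params$source_spacing)
  expo <- -params$spreading_coefficient / 10
  ln10_10 <- log(10) / 10
  E <- numeric(nr * nc)
  bh <- scene$building_height$values
  chunk <- 200L
  for (start in seq(1L, nrow(src), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(src))
    for (j in idx) {
      d <- sqrt((px - src[j, "x"])^2 + (py - src[j, "y"])^2)
      dd <- pmax(d, params$d0)
      pen <- params$ground_absorption * (d / 1000) * veg +
        params$elevation_penalty * pmax(0, elev_r - elev_s[j])
      if (params$shielding_db > 0) {
        pen <- pen + params$shielding_db *
          path_blocked(px, py, src[j, "x"], src[j, "y"], bh, grid)
      }
      E <- E + 10^(base_db[j] / 10) * (dd / params$d0)^expo * exp(-ln10_10 * pen)
    }
  }
  out <- grid
  out$values <- matrix(ifelse(E > 0, 10 * log10(E), NA_real_), nr, nc)
  out$units <- "dB(A)"
  out
}

# 0/1 per receiver: does the straight path to the source cross a built cell
# (sampled every half cell, end cells excluded)? Meant for small scenes.
path_blocked <- function(px, py, sx, sy, bh, grid) {
  blocked <- numeric(length(px))
  steps <- 24L
  fr <- seq(1 / (steps + 1), steps / (steps + 1), length.out = steps)
  nr <- nrow(bh); nc <- ncol(bh)
  for (f in fr) {
    qx <- px + f * (sx - px)
    qy <- py + f * (sy - py)
    col <- floor((qx - grid$origin_x) / grid$cell_size) + 1L
    row <- floor((grid$origin_y - qy) / grid$cell_size) + 1L
    ok <- col >= 1L & col <= nc & row >= 1L & row <= nr
    hit <- ok & bh[cbind(pmin(pmax(row, 1L), nr), pmin(pmax(col, 1L), nc))] > 0
    blocked[hit] <- 1
  }
  blocked
}

#' Known-coefficient linear reference surface
#'
#' Parameter-recovery fixture: builds a reference Lden surface as a known
#' linear combination of a feature stack's columns plus Gaussian noise, so
#' OLS fitting can be checked against ground truth (exact recovery at
#' `noise_sd = 0`; recovery within sampling error otherwise).
#'
#' @param stack A [build_feature_stack()] result.
#' @param betas Coefficient vector, intercept first (length = stack width + 1).
#' @param noise_sd Gaussian noise standard deviation in dB(A).
#' @param seed Integer seed for the noise draw.
#' @return A [noise_raster] in dB(A) (NA outside the stack mask).
#' @export
generate_linear_lden <- function(stack, betas, noise_sd = 0, seed = 1) {
  p <- ncol(stack$values)
  if (length(betas) != p + 1)
    stop(sprintf("betas must have length %d (intercept + %d features), got %d",
                 p + 1, p, length(betas)), call. = FALSE)
  set.seed(as.integer(seed))
  lin <- betas[1] + drop(stack$values %*% betas[-1])
  lin <- lin + stats::rnorm(length(lin), 0, noise_sd)
  lin[!stack$mask] <- NA_real_
  out <- stack$grid
  out$values <- matrix(lin, nrow(out$values), ncol(out$values))
  out$units <- "dB(A)"
  out
}
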