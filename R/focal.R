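# FFT-based "same"-size 2-D convolution with zero padding. Kernels here are
# symmetric, so convolution equals correlation and no flipping is needed.
convolve2d <- function(x, k) {
  nr <- nrow(x); nc <- ncol(x)
  kr <- nrow(k); kc <- ncol(k)
  pr <- stats::nextn(nr + kr - 1L, c(2, 3, 5))
  pc <- stats::nextn(nc + kc - 1L, c(2, 3, 5))
  X <- matrix(0, pr, pc); X[1:nr, 1:nc] <- x
  K <- matrix(0, pr, pc); K[1:kr, 1:kc] <- k
  full <- Re(stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE)) / (pr * pc)
  off_r <- (kr - 1L) %/% 2L
  off_c <- (kc - 1L) %/% 2L
  full[(1L + off_r):(nr + off_r), (1L + off_c):(nc + off_c)]
}

# circular window membership: offsets whose centre-to-centre distance is
# within `radius` metres (the focal cell itself included)
circular_kernel <- function(radius, cell_size) {
  m <- floor(radius / cell_size)
  idx <- seq(-m, m)
  d <- outer(idx, idx, function(i, j) sqrt(i^2 + j^2) * cell_size)
  (d <= radius) * 1
}

#' Canonical moving-window radii
#'
#' The eight systematically scaled neighbourhood radii (metres) used for all
#' contextual predictors. Their log-like spacing mirrors the logarithmic
#' attenuation of sound with distance.
#' @export
canonical_radii <- function() c(12.5, 25, 50, 100, 200, 400, 800, 1600)

#' Focal (moving-window) statistic
#'
#' Per-cell aggregate over all cells whose centres lie within `radius`
#' metres of the focal cell centre (a circular window). `mean` is
#' normalised by the number of in-domain, non-missing window cells, so
#' edge cells average over what is available; `sum` is left truncated at
#' the edges. Missing cells contribute nothing.
#'
#' @param raster A [noise_raster].
#' @param radius Window radius in metres.
#' @param stat `"sum"` or `"mean"`.
#' @return A [noise_raster]; missing cells of the input stay missing.
#' @export
focal_statistic <- function(raster, radius, stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  stopifnot(radius > 0)
  v <- raster$values
  ok <- !is.na(v)
  v0 <- ifelse(ok, v, 0)
  k <- circular_kernel(radius, raster$cell_size)
  s <- convolve2d(v0, k)
  if (stat == "mean") {
    n <- round(convolve2d(ok * 1, k))  # counts are integers; drop FFT noise
    s <- ifelse(n > 0, s / pmax(n, 1), NA_real_)
  }
  s[!ok] <- NA_real_
  out <- raster
  out$values <- s
  out
}

#' Topographic position index
#'
#' TPI = height of the focal cell minus the mean height of its circular
#' neighbourhood (the focal cell itself excluded from the mean). Positive
#' values mark locations superior to (higher than) their surroundings,
#' negative values mark valley or courtyard positions. Applied to a DEM it
#' captures terrain position; applied to a building-height model it
#' captures urban-morphology position and hence the volume available for
#' sound propagation. Cells with no in-window neighbour get 0.
#'
#' @param raster A [noise_raster] of heights (m).
#' @param radius Neighbourhood radius in metres.
#' @return A [noise_raster] (same units as input).
#' @export
tpi <- function(raster, radius) {
  v <- raster$values
  ok <- !is.na(v)
  v0 <- ifelse(ok, v, 0)
  k <- circular_kernel(radius, raster$cell_size)
  s <- convolve2d(v0, k)                  # window sum incl. centre
  n <- round(convolve2d(ok * 1, k))       # window count incl. centre
  nb <- pmax(n - 1, 0)
  res <- ifelse(nb > 0, v - (s - v0) / pmax(nb, 1), 0)
  res[!ok] <- NA_real_
  out <- raster
  out$values <- res
  out
}

#' Land-cover class fraction
#'
#' Percentage (0-100) of in-window cells carrying the given land-cover
#' class, per cell, over the circular window. Fractions over all seven
#' classes partition 100 exactly at every cell.
#'
#' @param landcover A [noise_raster] of integer classes 1..7.
#' @param class_id Class to measure (1 artificial, 2 open soil, 3 high
#'   seasonal vegetation, 4 high perennial vegetation, 5 low seasonal
#'   vegetation, 6 low perennial vegetation, 7 water).
#' @param radius Window radius in metres.
#' @return A [noise_raster] (percent).
#' @export
landcover_fraction <- function(landcover, class_id, radius) {
  if (!class_id %in% 1:7) stop("unknown land-cover class: ", class_id,
                               call. = FALSE)
  ind <- landcover
  ind$values <- ifelse(is.na(landcover$values), NA_real_,
                       (landcover$values == class_id) * 1)
  out <- focal_statistic(ind, radius, "mean")
  out$values <- out$values * 100
  out$units <- "%"
  out
}

#' Land-cover class labels
#' @export
landcover_classes <- function() {
  c(artificial = 1L, open_soil = 2L, high_seasonal_veg = 3L,
    high_perennial_veg = 4L, low_seasonal_veg = 5L,
    low_perennial_veg = 6L, water = 7L)
}

#' Log-proximity to roads of a type
#'
#' The proximity predictor: per-cell distance (m) to the nearest non-tunnel
#' segment of the type, transformed as `log10(d + 1)` so that a cell on the
#' road maps to 0 and the exponential decay of sound with distance becomes
#' approximately linear in the predictor. The +1 m offset makes the
#' transform defined at d = 0.
#'
#' @inheritParams rasterize_road_length
#' @return A [noise_raster] (log10 metres). When the network holds no
#'   segment of the type the column is a constant large-distance sentinel,
#'   flagged with attribute `constant_fill = TRUE`.
#' @export
proximity_feature <- function(roads, grid, road_type) {
  d <- road_distance(roads, grid, road_type)
  out <- d
  out$values <- log10(d$values + 1)
  out$units <- "log10(m)"
  attr(out, "constant_fill") <- isTRUE(attr(d, "constant_fill"))
  out
}
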