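#' Generate a complete synthetic study scene
#'
#' Builds a reproducible synthetic study area emulating the four inputs of a
#' road-noise LUR study: a terrain DEM shaped as a river valley, a
#' hierarchical road network touching all six functional road types (with a
#' short tunnel on the trunk road), clustered building blocks along the
#' residential streets, a seven-class land-cover mosaic, and two zone
#' layers — admin districts for spatially blocked cross-validation and
#' settlement-structure (land-use) zones for blocking and stratification.
#' All rasters share the 10-m analysis grid; every cell carries exactly one
#' land-cover class. The same seed reproduces the scene bit for bit.
#'
#' @param seed Integer seed driving all randomness in the scene.
#' @param n_rows,n_cols Grid dimensions (>= 50; all six road types are
#'   guaranteed present at any allowed size, with richer layouts on larger
#'   grids).
#' @param cell_size Cell edge length in metres (default 10).
#' @return An object of class `noise_scene`: a list with elements `dem`,
#'   `building_height`, `landcover` (all [noise_raster]), `roads`
#'   ([road_network]), `admin_zones`, `landuse_zones` ([zone_set]) and
#'   `seed`.
#' @examples
#' sc <- generate_scene(seed = 1, n_rows = 60, n_cols = 60)
#' table(sc$landcover$values)
#' @export
generate_scene <- function(seed, n_rows, n_cols, cell_size = 10) {
  if (n_rows < 50 || n_cols < 50)
    stop("grid too small for the road hierarchy: need at least 50 x 50 cells",
         call. = FALSE)
  set.seed(as.integer(seed))
  nr <- as.integer(n_rows); nc <- as.integer(n_cols); cs <- cell_size
  W <- nc * cs; H <- nr * cs
  template <- noise_raster(matrix(0, nr, nc), origin_x = 0, origin_y = H,
                           cell_size = cs)
  cc <- cell_centers(template)
  X <- matrix(rep(cc$x, each = nr), nr, nc)
  Y <- matrix(rep(cc$y, times = nc), nr, nc)

  # --- terrain: a meandering river valley with smooth random relief -------
  phase <- stats::runif(1, 0, 2 * pi)
  river_x <- function(y) W * (0.30 + 0.06 * sin(2 * pi * y / H + phase))
  XR <- river_x(Y)
  relief <- smooth_field(nr, nc, cs, range_m = 12 * cs)
  dem_v <- 65 * (abs(X - XR) / W)^1.3 + 8 * relief
  dem_v <- dem_v - min(dem_v)
  dem <- template; dem$values <- dem_v; dem$units <- "m"

  # --- roads: one hierarchical network on the flatter east bank -----------
  jit <- function(s) stats::runif(1, -s, s)
  path_y <- seq(H * 0.98, H * 0.02, length.out = 21)
  motorway <- cbind(W * 0.84 + W * 0.015 * sin(2 * pi * path_y / H * 1.5 + jit(1)),
                    path_y)
  trunk_mid_y <- H * (0.60 + jit(0.03))
  trunk_a <- cbind(seq(W * 0.84, W * 0.50, length.out = 8),
                   trunk_mid_y + H * 0.01 * sin(seq(0, pi, length.out = 8)))
  trunk_b <- cbind(seq(W * 0.50, W * 0.47, length.out = 2),
                   seq(trunk_mid_y, trunk_mid_y - H * 0.08, length.out = 2))
  trunk_c <- cbind(seq(W * 0.47, W * 0.43, length.out = 8),
                   seq(trunk_mid_y - H * 0.08, H * 0.04, length.out = 8))
  prim_y <- seq(H * 0.97, H * 0.03, length.out = 25)
  primary1 <- cbind(river_x(prim_y) + 8 * cs, prim_y)
  primary2 <- cbind(seq(W * 0.10, W * 0.84, length.out = 12),
                    H * (0.50 + jit(0.02)) + H * 0.008 * sin(seq(0, 2, length.out = 12)))
  sec_y1 <- H * (0.28 + jit(0.03)); sec_y2 <- H * (0.76 + jit(0.03))
  secondary1 <- cbind(seq(river_x(sec_y1) + 8 * cs, W * 0.84, length.out = 8),
                      sec_y1 + H * 0.005 * sin(seq(0, 3, length.out = 8)))
  secondary2 <- cbind(seq(river_x(sec_y2) + 8 * cs, W * 0.84, length.out = 8),
                      sec_y2 + H * 0.005 * cos(seq(0, 3, length.out = 8)))
  # settlement block centres on the east bank
  blocks <- rbind(
    c(W * (0.62 + jit(0.02)), H * (0.56 + jit(0.02))),
    c(W * (0.56 + jit(0.02)), H * (0.31 + jit(0.02))),
    c(W * (0.68 + jit(0.02)), H * (0.74 + jit(0.02)))
  )
  tert <- lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    tx <- seq(b[1], W * 0.84, length.out = 6)
    cbind(tx, b[2] + (X_amp <- H * 0.01) * sin(seq(0, 2, length.out = 6)) +
            (i - 2) * H * 0.01)
  })
  res_segs <- list()
  half <- 1.5 * 8 * cs  # residential block half-extent: 3 streets, 80-m spacing
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    off <- seq(-half, half, by = 8 * cs)
    for (o in off) {
      res_segs[[length(res_segs) + 1L]] <-
        cbind(c(b[1] - half, b[1] + half), c(b[2] + o, b[2] + o))
      res_segs[[length(res_segs) + 1L]] <-
        cbind(c(b[1] + o, b[1] + o), c(b[2] - half, b[2] + half))
    }
  }
  geoms <- c(list(motorway, trunk_a, trunk_b, trunk_c, primary1, primary2,
                  secondary1, secondary2), tert, res_segs)
  types <- c("motorway", "trunk", "trunk", "trunk", "primary", "primary",
             "secondary", "secondary", rep("tertiary", length(tert)),
             rep("residential", length(res_segs)))
  lanes <- c(4L, 3L, 3L, 3L, 2L, 2L, 2L, 2L, rep(1L, length(tert)),
             rep(1L, length(res_segs)))
  tunnel <- rep(FALSE, length(geoms)); tunnel[3] <- TRUE  # trunk_b runs underground
  geoms <- lapply(geoms, clamp_to_extent, W = W, H = H)
  roads <- road_network(types, geoms, lanes, tunnel)

  # --- buildings: clustered blocks along the residential streets ----------
  dres <- road_distance(roads, template, "residential")$values
  dprim <- road_distance(roads, template, "primary")$values
  bh <- matrix(0, nr, nc)
  cand <- dres < 4.5 * cs
  pick <- cand & (matrix(stats::runif(nr * nc), nr, nc) < 0.55)
  bh[pick] <- stats::runif(sum(pick), 5, 25)
  tall <- dprim < 3 * cs & matrix(stats::runif(nr * nc), nr, nc) < 0.12
  bh[tall] <- stats::runif(sum(tall), 10, 30)
  building_height <- template; building_height$values <- bh
  building_height$units <- "m"

  # --- land cover ----------------------------------------------------------
  f1 <- smooth_field(nr, nc, cs, range_m = 18 * cs)  # biomass gradient
  f2 <- smooth_field(nr, nc, cs, range_m = 18 * cs)  # seasonality gradient
  lc <- matrix(NA_real_, nr, nc)
  q <- stats::quantile(f1, c(0.04, 0.35, 0.65))
  lc[f1 <= q[1]] <- 2                               # open soil (rare)
  lc[f1 > q[1] & f1 <= q[2]] <- ifelse(f2[f1 > q[1] & f1 <= q[2]] > 0, 5, 6)
  lc[f1 > q[2] & f1 <= q[3]] <- ifelse(f2[f1 > q[2] & f1 <= q[3]] > 0, 5, 6)
  lc[f1 > q[3]] <- ifelse(f2[f1 > q[3]] > 0, 3, 4)
  lc[abs(X - XR) < 3 * cs] <- 7                     # river corridor
  lc[bh > 0 | dres < 1.5 * cs] <- 1                 # built-up / sealed
  for (cl in 1:7) {                                 # guarantee all classes
    if (!any(lc == cl)) {
      rr <- ((cl - 1L) * 5L + 2L):((cl - 1L) * 5L + 4L)
      lc[rr, 2:4] <- cl
    }
  }
  landcover <- template; landcover$values <- lc; landcover$units <- "class"

  # --- zones ---------------------------------------------------------------
  xs <- W * cumsum(c(0, 0.33 + jit(0.04), 0.33 + jit(0.04)))
  xs <- c(xs, W)
  ys <- H * cumsum(c(0, 0.33 + jit(0.04), 0.33 + jit(0.04)))
  ys <- c(ys, H)
  rects <- list(); ids <- character()
  for (i in 1:3) for (j in 1:3) {
    rects[[length(rects) + 1L]] <- rect_ring(xs[j], xs[j + 1], ys[i], ys[i + 1])
    ids <- c(ids, sprintf("D%d", length(ids) + 1L))
  }
  admin_zones <- zone_set(ids, rects, kind = "admin")

  lx <- c(0, W * (0.34 + jit(0.03)), W * (0.67 + jit(0.03)), W)
  ly <- c(0, H * (0.5 + jit(0.04)), H)
  lz <- list(); lids <- character(); llab <- character()
  for (i in 1:2) for (j in 1:3) {
    ring <- rect_ring(lx[j], lx[j + 1], ly[i], ly[i + 1])
    inrect <- X >= lx[j] & X < lx[j + 1] & Y >= ly[i] & Y < ly[i + 1]
    a <- mean(lc[inrect] == 1); w <- mean(lc[inrect] == 7)
    h <- mean(lc[inrect] %in% c(3, 4))
    lab <- if (a > 0.10) "urban" else if (w > 0.08) "riverine"
           else if (h > 0.45) "forest" else "open_agrarian"
    lz[[length(lz) + 1L]] <- ring
    lids <- c(lids, sprintf("L%d", length(lids) + 1L))
    llab <- c(llab, lab)
  }
  landuse_zones <- zone_set(lids, lz, llab, kind = "landuse")

  structure(
    list(dem = dem, building_height = building_height, landcover = landcover,
         roads = roads, admin_zones = admin_zones,
         landuse_zones = landuse_zones, seed = as.integer(seed)),
    class = "noise_scene"
  )
}

#' @export
print.noise_scene <- function(x, ...) {
  v <- x$dem$values
  cat(sprintf("<noise_scene> %d x %d cells @ %g m, seed %d\n",
              nrow(v), ncol(v), x$dem$cell_size, x$seed))
  cat(sprintf("  roads: %d segments (%s)\n", nrow(x$roads),
              paste(names(table(droplevels(x$roads$road_type))), collapse = ", ")))
  cat(sprintf("  built-up cells: %d; land-cover classes: %s\n",
              sum(x$building_height$values > 0),
              paste(sort(unique(as.vector(x$landcover$values))), collapse = ",")))
  cat(sprintf("  zones: %d admin, %d land-use\n", nrow(x$admin_zones),
              nrow(x$landuse_zones)))
  invisible(x)
}

# mean-zero, unit-sd smooth Gaussian random field (white noise smoothed over
# a circular window of the given range)
smooth_field <- function(nr, nc, cell_size, range_m) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  k <- circular_kernel(range_m, cell_size)
  s <- convolve2d(z, k / sum(k))
  (s - mean(s)) / stats::sd(s)
}

rect_ring <- function(x0, x1, y0, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

clamp_to_extent <- function(g, W, H) {
  g[, 1] <- pmin(pmax(g[, 1], 0.5), W - 0.5)
  g[, 2] <- pmin(pmax(g[, 2], 0.5), H - 0.5)
  g
}
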