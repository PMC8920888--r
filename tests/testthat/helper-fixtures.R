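# Shared fixtures, built once per test run and cached. Seeds are fixed
# design choices of the test-bed scenes, not tuning knobs.

.fixtures <- new.env(parent = emptyenv())

# number of cells in a circular window (centre-distance rule)
circular_kernel_size <- function(radius, cs) {
  m <- floor(radius / cs)
  idx <- seq(-m, m)
  sum(outer(idx, idx, function(i, j) sqrt(i^2 + j^2) * cs) <= radius)
}

rect_ring_test <- function(x0, x1, y0, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# flat featureless raster helper
flat_raster <- function(value, nr = 10, nc = 10, cell_size = 10) {
  noise_raster(matrix(value, nr, nc), cell_size = cell_size)
}

# a one-segment road network
one_road <- function(coords, type = "motorway", lanes = 1L, tunnel = FALSE) {
  road_network(type, list(as.matrix(coords)), lanes = lanes, tunnel = tunnel)
}

# minimal hand-built scene: flat ground, no vegetation effects, no buildings,
# a single road; used for controlled acoustic checks
mini_scene <- function(roads, nr = 21, nc = 21, landcover_class = 1) {
  template <- noise_raster(matrix(0, nr, nc))
  structure(list(
    dem = template,
    building_height = template,
    landcover = noise_raster(matrix(landcover_class, nr, nc)),
    roads = roads, seed = 0L
  ), class = "noise_scene")
}

# acoustic params with ground/elevation terms disabled (pure spreading)
pure_spreading <- function(...) {
  acoustic_params(ground_absorption = 0, elevation_penalty = 0, ...)
}

# medium scene shared by feature-level tests
small_fixture <- function() {
  if (is.null(.fixtures$small)) {
    scene <- generate_scene(seed = 7, n_rows = 60, n_cols = 60)
    lden <- simulate_lden(scene)
    .fixtures$small <- list(scene = scene, lden = lden)
  }
  .fixtures$small
}

# the full-size campaign test-bed: 300 x 300 scene, acoustic reference map,
# radius-selected 21-column stack, zone label rasters
campaign_fixture <- function() {
  if (is.null(.fixtures$big)) {
    scene <- generate_scene(seed = 20, n_rows = 300, n_cols = 300)
    lden <- simulate_lden(scene)
    stack <- build_feature_stack(scene)
    screen_sample <- draw_sample(lden, "stratified_lden", 1000, seed = 101,
                                 strata = lden_strata(lden))
    sel <- suppressWarnings(select_radii(stack, screen_sample))
    .fixtures$big <- list(
      scene = scene, lden = lden, stack = sel$stack,
      candidate_stack = stack,
      admin = rasterize_zones(scene$admin_zones, scene$dem, by = "id"),
      landuse = rasterize_zones(scene$landuse_zones, scene$dem, by = "label")
    )
  }
  .fixtures$big
}

# brute-force focal oracle: direct double loop over window offsets
brute_focal <- function(r, radius, stat = "sum") {
  v <- r$values; cs <- r$cell_size
  nr <- nrow(v); nc <- ncol(v)
  m <- floor(radius / cs)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(v[i, j])) next
    acc <- 0; cnt <- 0
    for (di in -m:m) for (dj in -m:m) {
      if (sqrt(di^2 + dj^2) * cs > radius) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || is.na(v[ii, jj])) next
      acc <- acc + v[ii, jj]; cnt <- cnt + 1
    }
    out[i, j] <- if (stat == "sum") acc else acc / cnt
  }
  out
}

# brute-force TPI oracle (centre excluded from the neighbourhood mean)
brute_tpi <- function(r, radius) {
  v <- r$values; cs <- r$cell_size
  nr <- nrow(v); nc <- ncol(v)
  m <- floor(radius / cs)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(v[i, j])) next
    acc <- 0; cnt <- 0
    for (di in -m:m) for (dj in -m:m) {
      if (di == 0 && dj == 0) next
      if (sqrt(di^2 + dj^2) * cs > radius) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || is.na(v[ii, jj])) next
      acc <- acc + v[ii, jj]; cnt <- cnt + 1
    }
    out[i, j] <- if (cnt > 0) v[i, j] - acc / cnt else 0
  }
  out
}

# brute-force per-cell distance to a polyline set (point-to-segment formula)
brute_distance <- function(grid, geoms) {
  cc <- cell_centers(grid)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  out <- matrix(Inf, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    p <- c(cc$x[j], cc$y[i])
    for (g in geoms) {
      for (e in seq_len(nrow(g) - 1)) {
        a <- g[e, ]; b <- g[e + 1, ]
        v <- b - a; L2 <- sum(v^2)
        t <- if (L2 == 0) 0 else max(0, min(1, sum((p - a) * v) / L2))
        out[i, j] <- min(out[i, j], sqrt(sum((p - a - t * v)^2)))
      }
    }
  }
  out
}

# independent normal-equations OLS oracle with classical inference
brute_ols <- function(X, y) {
  Xd <- cbind(1, as.matrix(X))
  XtX_inv <- solve(t(Xd) %*% Xd)
  beta <- XtX_inv %*% t(Xd) %*% y
  res <- y - Xd %*% beta
  n <- length(y); p <- ncol(Xd)
  sigma2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(XtX_inv) * sigma2)
  tval <- drop(beta) / se
  list(beta = drop(beta), se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), n - p))
}
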