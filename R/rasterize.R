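#' Lane-weighted road length per cell
#'
#' Rasterizes one road type onto the analysis grid: each cell receives the
#' summed in-cell clipped length of all non-tunnel segments of that type,
#' multiplied by the segment's lane count (the recommended emission weight
#' when traffic counts are unavailable). Cells without roads are 0; the
#' result is in metres.
#'
#' The clipping is exact: every polyline edge is cut at the grid lines it
#' crosses and each piece is attributed to the cell containing its midpoint,
#' so total length is conserved to floating-point accuracy.
#'
#' @param roads A [road_network].
#' @param grid A [noise_raster] defining the target geometry.
#' @param road_type One of the six road types.
#' @return A [noise_raster] (metres of lane-weighted road per cell).
#' @export
rasterize_road_length <- function(roads, grid, road_type) {
  road_type <- match.arg(road_type, road_type_levels())
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cs <- grid$cell_size
  acc <- matrix(0, nr, nc)
  keep <- which(!roads$tunnel & roads$road_type == road_type)
  for (k in keep) {
    g <- roads$geometry[[k]]
    w <- roads$lanes[k]
    for (e in seq_len(nrow(g) - 1L)) {
      p1 <- g[e, ]; p2 <- g[e + 1L, ]
      len <- sqrt(sum((p2 - p1)^2))
      if (len == 0) next
      # parametric positions of grid-line crossings along the edge
      tx <- ty <- numeric(0)
      if (p1[1] != p2[1]) {
        xs <- grid$origin_x + cs * seq(0, nc)
        xs <- xs[xs > min(p1[1], p2[1]) & xs < max(p1[1], p2[1])]
        tx <- (xs - p1[1]) / (p2[1] - p1[1])
      }
      if (p1[2] != p2[2]) {
        ys <- grid$origin_y - cs * seq(0, nr)
        ys <- ys[ys > min(p1[2], p2[2]) & ys < max(p1[2], p2[2])]
        ty <- (ys - p1[2]) / (p2[2] - p1[2])
      }
      ts <- sort(unique(c(0, tx, ty, 1)))
      mid_t <- (ts[-1] + ts[-length(ts)]) / 2
      seg_len <- diff(ts) * len
      mx <- p1[1] + mid_t * (p2[1] - p1[1])
      my <- p1[2] + mid_t * (p2[2] - p1[2])
      col <- floor((mx - grid$origin_x) / cs) + 1L
      row <- floor((grid$origin_y - my) / cs) + 1L
      ok <- col >= 1L & col <= nc & row >= 1L & row <= nr & seg_len > 0
      for (i in which(ok)) acc[row[i], col[i]] <- acc[row[i], col[i]] + seg_len[i] * w
    }
  }
  noise_raster(acc, origin_x = grid$origin_x, origin_y = grid$origin_y,
               cell_size = cs, units = "m")
}

# minimum distance from points (px, py) to a polyline, vectorised over points
dist_to_polyline <- function(px, py, g) {
  d2 <- rep(Inf, length(px))
  for (e in seq_len(nrow(g) - 1L)) {
    ax <- g[e, 1]; ay <- g[e, 2]
    bx <- g[e + 1L, 1]; by <- g[e + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    if (L2 == 0) {
      dd <- (px - ax)^2 + (py - ay)^2
    } else {
      t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
      dd <- (px - ax - t * vx)^2 + (py - ay - t * vy)^2
    }
    d2 <- pmin(d2, dd)
  }
  sqrt(d2)
}

#' Distance to the nearest road of a type
#'
#' Per-cell Euclidean distance (metres, from the cell centre) to the nearest
#' non-tunnel segment of the given road type. This is the raw distance
#' surface behind the log-proximity predictor.
#'
#' @inheritParams rasterize_road_length
#' @return A [noise_raster] (metres). If the network holds no segment of the
#'   type, a constant sentinel surface (the grid diagonal) is returned with
#'   attribute `constant_fill = TRUE`.
#' @export
road_distance <- function(roads, grid, road_type) {
  road_type <- match.arg(road_type, road_type_levels())
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cc <- cell_centers(grid)
  px <- rep(cc$x, each = nr)
  py <- rep(cc$y, times = nc)
  keep <- which(!roads$tunnel & roads$road_type == road_type)
  if (!length(keep)) {
    diag_m <- sqrt((nr^2 + nc^2)) * grid$cell_size
    out <- noise_raster(matrix(diag_m, nr, nc), origin_x = grid$origin_x,
                        origin_y = grid$origin_y, cell_size = grid$cell_size,
                        units = "m")
    attr(out, "constant_fill") <- TRUE
    return(out)
  }
  d <- rep(Inf, nr * nc)
  for (k in keep) d <- pmin(d, dist_to_polyline(px, py, roads$geometry[[k]]))
  noise_raster(matrix(d, nr, nc), origin_x = grid$origin_x,
               origin_y = grid$origin_y, cell_size = grid$cell_size,
               units = "m")
}
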