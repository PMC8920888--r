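#' Zone polygons for blocking and stratification
#'
#' A zone set is a tibble with one row per polygon: `zone_id` (unique),
#' `label` (a class name, e.g. a district name or a settlement-structure
#' class; labels may repeat across polygons of the same class) and
#' `geometry` (list column of closed-ring n x 2 coordinate matrices in
#' metres). Zones drive the spatially blocked cross-validations and the
#' land-use stratified sampling scheme. Polygons need not be rectangular;
#' a cell belongs to the zone containing its centre.
#'
#' @param zone_id Unique ids.
#' @param label Class labels (default: the ids).
#' @param geometry List of n x 2 matrices (rings; first point need not be
#'   repeated at the end).
#' @param kind `"admin"` or `"landuse"`.
#' @return A tibble of class `zone_set`.
#' @export
zone_set <- function(zone_id, geometry, label = as.character(zone_id),
                     kind = c("admin", "landuse")) {
  kind <- match.arg(kind)
  if (anyDuplicated(zone_id)) stop("zone ids must be unique", call. = FALSE)
  geometry <- lapply(geometry, function(g) {
    g <- as.matrix(g)
    stopifnot(ncol(g) == 2, nrow(g) >= 3, !anyNA(g))
    dimnames(g) <- NULL
    g
  })
  out <- tibble::tibble(zone_id = as.character(zone_id),
                        label = as.character(label), geometry = geometry)
  attr(out, "kind") <- kind
  class(out) <- c("zone_set", class(out))
  out
}

# ray-casting point-in-polygon, vectorised over points; boundary points count
# as inside (even-odd rule with half-open edges keeps partitions unambiguous)
points_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ye[i] > py))
    if (any(crosses)) {
      xint <- xs[i] + (py[crosses] - ys[i]) / (ye[i] - ys[i]) * (xe[i] - xs[i])
      hit <- px[crosses] < xint
      inside[crosses] <- xor(inside[crosses], hit)
    }
  }
  inside
}

#' Rasterize zones onto the analysis grid
#'
#' Labels every cell by the zone whose polygon contains its centre; cells
#' covered by no zone become `NA`. Overlapping zones are an error, because
#' ambiguous membership would make spatial blocking ill-defined.
#'
#' @param zones A [zone_set].
#' @param grid A [noise_raster] defining the target geometry.
#' @param by `"id"` labels cells by polygon (1..n in table order);
#'   `"label"` by class label (1..n distinct labels, useful when several
#'   polygons share a settlement-structure class).
#' @return A [noise_raster] of integer labels with a `levels` attribute
#'   mapping label codes to zone ids / class labels.
#' @export
rasterize_zones <- function(zones, grid, by = c("id", "label")) {
  by <- match.arg(by)
  cc <- cell_centers(grid)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  px <- rep(cc$x, each = nr)
  py <- rep(cc$y, times = nc)
  lab <- rep(NA_integer_, nr * nc)
  keys <- if (by == "id") zones$zone_id else zones$label
  lev <- unique(keys)
  for (i in seq_len(nrow(zones))) {
    inside <- points_in_ring(px, py, zones$geometry[[i]])
    code <- match(keys[i], lev)
    clash <- inside & !is.na(lab) & lab != code
    if (any(clash)) {
      stop(sprintf("overlapping zone polygons: cell centre claimed by both '%s' and '%s'",
                   lev[lab[which(clash)[1]]], keys[i]), call. = FALSE)
    }
    lab[inside] <- code
  }
  out <- noise_raster(matrix(as.double(lab), nr, nc),
                      origin_x = grid$origin_x, origin_y = grid$origin_y,
                      cell_size = grid$cell_size, units = "zone")
  attr(out, "levels") <- lev
  out
}

#' Read and write zone sets (GeoJSON)
#'
#' Zones are exchanged as GeoJSON FeatureCollections of Polygon features
#' with properties `id` and `label`.
#'
#' @param path File path.
#' @param kind `"admin"` or `"landuse"`.
#' @return A [zone_set].
#' @export
read_zones <- function(path, kind = c("admin", "landuse")) {
  kind <- match.arg(kind)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ids <- character(); labels <- character(); geoms <- list()
  for (f in gj$features %||% list()) {
    g <- f$geometry
    if (!identical(g$type, "Polygon"))
      stop("zone features must be Polygons, got: ", g$type, call. = FALSE)
    ring <- do.call(rbind, lapply(g$coordinates[[1]],
                                  function(xy) as.numeric(xy[1:2])))
    # drop explicit ring closure if present
    if (nrow(ring) > 3 && all(ring[1, ] == ring[nrow(ring), ]))
      ring <- ring[-nrow(ring), , drop = FALSE]
    geoms[[length(geoms) + 1L]] <- ring
    ids <- c(ids, as.character(f$properties$id %||% (length(ids) + 1L)))
    labels <- c(labels, as.character(f$properties$label %||% ids[length(ids)]))
  }
  zone_set(ids, geoms, labels, kind = kind)
}

#' @rdname read_zones
#' @param zones A [zone_set] to write.
#' @export
write_zones <- function(zones, path) {
  feats <- purrr::pmap(
    list(zones$zone_id, zones$label, zones$geometry),
    function(id, lb, g) {
      ring <- rbind(g, g[1, ])
      list(
        type = "Feature",
        properties = list(id = id, label = lb),
        geometry = list(
          type = "Polygon",
          coordinates = list(lapply(seq_len(nrow(ring)),
                                    function(i) c(ring[i, 1], ring[i, 2])))
        )
      )
    }
  )
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
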