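#' Typed road networks
#'
#' A road network is a tibble with one row per segment: `segment_id`,
#' `road_type` (one of the six functional classes `motorway`, `trunk`,
#' `primary`, `secondary`, `tertiary`, `residential`), `lanes` (integer,
#' >= 1), `tunnel` (logical) and `geometry` (a list column of n x 2
#' coordinate matrices in metres). Road type is the emission proxy used
#' throughout: there are no traffic counts, so functional class stands in
#' for traffic volume and speed. Tunnel segments are retained in the table
#' but carry no emission weight in any downstream computation.
#'
#' @param road_type Character vector of types (must be from the six-class set).
#' @param geometry List of numeric matrices with columns x, y (metres).
#' @param lanes Integer vector, defaults to 1.
#' @param tunnel Logical vector, defaults to FALSE.
#' @return A tibble of class `road_network`.
#' @export
road_network <- function(road_type, geometry, lanes = 1L, tunnel = FALSE) {
  road_type <- as.character(road_type)
  bad <- setdiff(unique(road_type), road_type_levels())
  if (length(bad)) stop("unknown road type(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!is.list(geometry)) geometry <- list(geometry)
  geometry <- lapply(geometry, function(g) {
    g <- as.matrix(g)
    if (ncol(g) != 2 || nrow(g) < 2 || anyNA(g) || !is.numeric(g))
      stop("malformed segment geometry: need a numeric n x 2 matrix with n >= 2",
           call. = FALSE)
    dimnames(g) <- NULL
    g
  })
  n <- length(geometry)
  out <- tibble::tibble(
    segment_id = seq_len(n),
    road_type = factor(road_type, levels = road_type_levels()),
    lanes = as.integer(rep_len(lanes, n)),
    tunnel = rep_len(as.logical(tunnel), n),
    geometry = geometry
  )
  if (any(out$lanes < 1L)) stop("lanes must be >= 1", call. = FALSE)
  class(out) <- c("road_network", class(out))
  out
}

#' @rdname road_network
#' @export
road_type_levels <- function() {
  c("motorway", "trunk", "primary", "secondary", "tertiary", "residential")
}

segment_length <- function(g) {
  d <- diff(g)
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

#' Total network length weighted by lanes
#'
#' Sum over non-tunnel segments (optionally of one type) of polyline length
#' times lane count, in metres.
#'
#' @param roads A [road_network].
#' @param road_type Optional single type to restrict to.
#' @export
network_length <- function(roads, road_type = NULL) {
  keep <- !roads$tunnel
  if (!is.null(road_type)) keep <- keep & roads$road_type == road_type
  if (!any(keep)) return(0)
  sum(vapply(roads$geometry[keep], segment_length, 0) * roads$lanes[keep])
}

#' Read and write road networks (GeoJSON)
#'
#' Roads are exchanged as GeoJSON FeatureCollections of LineString /
#' MultiLineString features with OSM-style properties: `highway` (mapped to
#' the six functional types), optional `lanes` (defaults to 1 when absent)
#' and optional `tunnel` (`"yes"`/`true`). Features whose `highway` value is
#' not in the mapping (e.g. `service`, `track`, `*_link`) are dropped with a
#' message reporting the count; features without a `highway` property are
#' skipped with a warning.
#'
#' @param path File path.
#' @param highway_map Named character vector mapping `highway` values to the
#'   six road types. The default is the identity map on the six types.
#' @return A [road_network].
#' @export
read_roads <- function(path, highway_map = NULL) {
  if (is.null(highway_map)) {
    highway_map <- stats::setNames(road_type_levels(), road_type_levels())
  }
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features %||% list()
  types <- character(); lanes <- integer(); tunnel <- logical()
  geoms <- list(); dropped <- 0L; skipped <- 0L
  for (f in feats) {
    hw <- f$properties$highway
    if (is.null(hw)) { skipped <- skipped + 1L; next }
    if (!hw %in% names(highway_map)) { dropped <- dropped + 1L; next }
    ln <- f$properties$lanes
    ln <- if (is.null(ln)) 1L else as.integer(ln)
    tu <- f$properties$tunnel
    tu <- !is.null(tu) && (isTRUE(tu) || identical(tu, "yes") || identical(tu, "true"))
    g <- f$geometry
    if (is.null(g$type) || is.null(g$coordinates))
      stop("malformed geometry in ", path, call. = FALSE)
    parts <- switch(g$type,
      LineString = list(g$coordinates),
      MultiLineString = g$coordinates,
      stop("unsupported geometry type: ", g$type, call. = FALSE)
    )
    for (p in parts) {
      m <- do.call(rbind, lapply(p, function(xy) as.numeric(xy[1:2])))
      if (!is.matrix(m) || nrow(m) < 2 || anyNA(m))
        stop("malformed geometry in ", path, call. = FALSE)
      geoms[[length(geoms) + 1L]] <- m
      types <- c(types, unname(highway_map[[hw]]))
      lanes <- c(lanes, ln)
      tunnel <- c(tunnel, tu)
    }
  }
  if (skipped) warning(skipped, " feature(s) without a highway property skipped",
                       call. = FALSE)
  if (dropped) message(dropped, " feature(s) with unmapped highway values dropped")
  if (!length(geoms)) {
    return(road_network(character(), list(), integer(), logical()))
  }
  road_network(types, geoms, lanes, tunnel)
}

#' @rdname read_roads
#' @param roads A [road_network] to write.
#' @export
write_roads <- function(roads, path) {
  feats <- purrr::pmap(
    list(roads$road_type, roads$lanes, roads$tunnel, roads$geometry),
    function(ty, ln, tu, g) {
      list(
        type = "Feature",
        properties = list(highway = as.character(ty), lanes = ln,
                          tunnel = if (tu) "yes" else "no"),
        geometry = list(
          type = "LineString",
          coordinates = lapply(seq_len(nrow(g)), function(i) c(g[i, 1], g[i, 2]))
        )
      )
    }
  )
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
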