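#' Georeferenced raster grid
#'
#' `noise_raster()` is the package's light-weight container for a single-band
#' georeferenced grid on a planar metric coordinate system: a numeric matrix
#' plus the top-left origin (metres), the cell size (metres, 10 m for all
#' standard analyses) and a unit label. Row 1 is the northernmost row; cell
#' extents are half-open `[x, x + cell_size)`. The centre of cell
#' `(r, c)` (1-based) lies at
#' `(origin_x + (c - 0.5) * cell_size, origin_y - (r - 0.5) * cell_size)`.
#' Missing cells are stored as `NA` and are excluded from every statistic;
#' the `nodata` sentinel is only used on disk.
#'
#' @param values Numeric matrix (row 1 = north).
#' @param origin_x,origin_y Coordinates of the top-left corner in metres.
#' @param cell_size Cell edge length in metres (> 0).
#' @param nodata Sentinel written to / recognised in files (default -9999).
#' @param units Free-text unit label, e.g. `"dB(A)"`, `"m"`, `"%"`.
#' @return An object of class `noise_raster`.
#' @examples
#' r <- noise_raster(matrix(1:12, 3, 4), cell_size = 10, units = "m")
#' raster_mean(r)
#' @export
noise_raster <- function(values, origin_x = 0, origin_y = nrow(values) * cell_size,
                         cell_size = 10, nodata = -9999, units = "") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(cell_size > 0)
  structure(
    list(values = values, origin_x = origin_x, origin_y = origin_y,
         cell_size = cell_size, nodata = nodata, units = units),
    class = "noise_raster"
  )
}

#' @export
print.noise_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<noise_raster> %d x %d cells @ %g m%s\n", nrow(v), ncol(v),
              x$cell_size, if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  cat(sprintf("  origin (top-left): (%g, %g)\n", x$origin_x, x$origin_y))
  ok <- !is.na(v)
  if (any(ok)) {
    cat(sprintf("  values: %.3g .. %.3g (mean %.4g), %d NA cells\n",
                min(v[ok]), max(v[ok]), mean(v[ok]), sum(!ok)))
  } else {
    cat("  values: all NA\n")
  }
  invisible(x)
}

#' @rdname noise_raster
#' @param x,r A `noise_raster`.
#' @export
raster_mean <- function(r) mean(r$values, na.rm = TRUE)

#' @rdname noise_raster
#' @export
raster_values <- function(r) r$values

#' Cell-centre coordinates
#'
#' Returns the x (easting) coordinates of all columns and y (northing)
#' coordinates of all rows of the cell centres, or a full per-cell tibble.
#'
#' @param r A `noise_raster`.
#' @return `cell_centers()` gives `list(x =, y =)`; `as_tibble()` one row per
#'   cell with `row`, `col`, `x`, `y`, `value`.
#' @export
cell_centers <- function(r) {
  list(
    x = r$origin_x + (seq_len(ncol(r$values)) - 0.5) * r$cell_size,
    y = r$origin_y - (seq_len(nrow(r$values)) - 0.5) * r$cell_size
  )
}

#' @exportS3Method tibble::as_tibble
as_tibble.noise_raster <- function(x, ...) {
  cc <- cell_centers(x)
  nr <- nrow(x$values); nc <- ncol(x$values)
  vals <- as.vector(x$values)  # grab before `x` is shadowed by the column
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = rep(cc$x, each = nr),
    y = rep(cc$y, times = nc),
    value = vals
  )
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$origin_x, a$origin_y, a$cell_size),
                     c(b$origin_x, b$origin_y, b$cell_size)))
}

stop_if_misaligned <- function(a, b, what = "rasters") {
  if (!same_geometry(a, b)) {
    stop(sprintf("%s do not share grid geometry (%dx%d @%gm vs %dx%d @%gm)",
                 what, nrow(a$values), ncol(a$values), a$cell_size,
                 nrow(b$values), ncol(b$values), b$cell_size), call. = FALSE)
  }
  invisible(TRUE)
}

# linear cell index (column-major, matching R matrices) from row/col
cell_index <- function(r, row, col) (col - 1L) * nrow(r$values) + row

#' Read and write rasters (ESRI ASCII grid)
#'
#' Rasters are exchanged in the ESRI ASCII grid format (`.asc`): a plain-text
#' single-band georeferenced raster with an `ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by the values, north row first.
#' Values are written with full double precision, so a write/read round trip
#' is bit exact.
#'
#' @param path File path.
#' @param expected_cell_size If not `NULL`, reading a raster with a different
#'   cell size is an error (the analysis grid is fixed at 10 m).
#' @param units Unit label to attach on read (the format itself carries none).
#' @return `read_raster()` a [noise_raster]; `write_raster()` the path,
#'   invisibly.
#' @export
read_raster <- function(path, expected_cell_size = NULL, units = "") {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) stop("not an ESRI ASCII grid: ", path, call. = FALSE)
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2 && grepl("^[A-Za-z_]+$", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("missing georeference header in ", path, call. = FALSE)
  if (!any(c("xllcorner", "yllcorner") %in% names(hdr)))
    stop("missing georeference (xllcorner/yllcorner) in ", path, call. = FALSE)
  cs <- hdr$cellsize
  if (!is.null(expected_cell_size) && !isTRUE(all.equal(cs, expected_cell_size))) {
    stop(sprintf("raster cell size %g does not match expected %g",
                 cs, expected_cell_size), call. = FALSE)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d in %s", nr * nc, length(vals), path),
         call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  noise_raster(m, origin_x = hdr$xllcorner,
               origin_y = hdr$yllcorner + nr * cs,
               cell_size = cs, nodata = nodata, units = units)
}

#' @rdname read_raster
#' @param r A [noise_raster] to write.
#' @export
write_raster <- function(r, path) {
  v <- r$values
  v[is.na(v)] <- r$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.17g", r$origin_x),
    sprintf("yllcorner %.17g", r$origin_y - nrow(v) * r$cell_size),
    sprintf("cellsize %.17g", r$cell_size),
    sprintf("NODATA_value %.17g", r$nodata)
  )
  body <- apply(v, 1, function(row) paste(sprintf("%.17g", row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
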