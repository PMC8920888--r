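#' Build the candidate predictor stack for a scene
#'
#' Assembles the full LUR predictor space on the analysis grid:
#' \itemize{
#'   \item 6 log-proximity columns, one per road type (no radius);
#'   \item 6 lane-weighted cumulated road-length columns (km) per radius;
#'   \item 1 building TPI and 1 terrain TPI column per radius;
#'   \item 7 land-cover fraction columns (percent) per radius.
#' }
#' With the canonical eight radii that is 6 + (6 + 1 + 1 + 7) x 8 = 126
#' candidate columns; radius selection (see [select_radii()]) later reduces
#' the 14 windowed variables to one radius each, leaving 21 columns.
#'
#' @param scene A [generate_scene()] result (or any list with elements
#'   `dem`, `building_height`, `landcover`, `roads`).
#' @param radii Window radii in metres (default [canonical_radii()]).
#' @return An object of class `feature_stack`: list with `specs` (tibble:
#'   `name`, `source`, `variable`, `aggregation`, `radius`), `values`
#'   (cells x columns matrix, column-major cell order), `grid` (template
#'   [noise_raster]) and `mask` (logical vector of valid cells).
#' @export
build_feature_stack <- function(scene, radii = canonical_radii()) {
  for (layer in c("dem", "building_height", "landcover", "roads")) {
    if (is.null(scene[[layer]]))
      stop("scene is missing layer: ", layer, call. = FALSE)
  }
  grid <- scene$dem
  n_cells <- length(grid$values)
  mask <- !is.na(grid$values) & !is.na(scene$landcover$values)
  specs <- list(); cols <- list()
  add <- function(name, source, variable, aggregation, radius, raster) {
    specs[[length(specs) + 1L]] <<- tibble::tibble(
      name = name, source = source, variable = variable,
      aggregation = aggregation, radius = radius)
    cols[[length(cols) + 1L]] <<- as.vector(raster$values)
  }
  for (ty in road_type_levels()) {
    add(paste0(ty, "_prox"), "roads", paste0(ty, "_prox"), "none", NA_real_,
        proximity_feature(scene$roads, grid, ty))
  }
  len_base <- lapply(road_type_levels(), function(ty)
    rasterize_road_length(scene$roads, grid, ty))
  names(len_base) <- road_type_levels()
  lc_names <- names(landcover_classes())
  for (r in radii) {
    for (ty in road_type_levels()) {
      lr <- focal_statistic(len_base[[ty]], r, "sum")
      lr$values <- lr$values / 1000  # km
      add(sprintf("%s_length_r%s", ty, r), "roads", paste0(ty, "_length"),
          "sum", r, lr)
    }
    add(sprintf("building_tpi_r%s", r), "buildings", "building_tpi", "tpi", r,
        tpi(scene$building_height, r))
    add(sprintf("terrain_tpi_r%s", r), "dem", "terrain_tpi", "tpi", r,
        tpi(scene$dem, r))
    for (cl in seq_along(lc_names)) {
      add(sprintf("lc_%s_r%s", lc_names[cl], r), "landcover",
          paste0("lc_", lc_names[cl]), "fraction", r,
          landcover_fraction(scene$landcover, cl, r))
    }
  }
  specs <- dplyr::bind_rows(specs)
  values <- do.call(cbind, cols)
  colnames(values) <- specs$name
  values[!as.vector(mask), ] <- NA_real_
  structure(list(specs = specs, values = values, grid = grid,
                 mask = as.vector(mask)),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> %d columns x %d cells (%d valid)\n",
              ncol(x$values), nrow(x$values), sum(x$mask)))
  print(dplyr::count(x$specs, .data$variable, name = "radii"), n = 5)
  invisible(x)
}

#' Design matrix at sample cells
#'
#' Extracts the stack columns at the given linear cell indices (e.g. the
#' `cell` column of a [draw_sample()] result) as a plain numeric matrix
#' ready for model fitting.
#'
#' @param stack A [build_feature_stack()] result.
#' @param cells Linear cell indices (column-major, as used throughout).
#' @return A `length(cells)` x `ncol(stack$values)` matrix.
#' @export
design_matrix <- function(stack, cells) {
  stack$values[cells, , drop = FALSE]
}

#' Subset a stack to named columns
#' @param stack A `feature_stack`.
#' @param names Column names to keep, in the desired order.
#' @export
stack_subset <- function(stack, names) {
  miss <- setdiff(names, stack$specs$name)
  if (length(miss)) stop("unknown stack columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  keep <- match(names, stack$specs$name)
  stack$specs <- stack$specs[keep, ]
  stack$values <- stack$values[, keep, drop = FALSE]
  stack
}

#' Single stack column as a raster
#' @param stack A `feature_stack`.
#' @param name Column name.
#' @export
feature_raster <- function(stack, name) {
  j <- match(name, stack$specs$name)
  if (is.na(j)) stop("unknown stack column: ", name, call. = FALSE)
  out <- stack$grid
  out$values <- matrix(stack$values[, j], nrow(out$values), ncol(out$values))
  out$units <- ""
  out
}

#' On-road Lden summary and ANOVA by road type
#'
#' Checks that the six functional road types are a meaningful emission
#' proxy: for the cells each type runs through (non-tunnel segments), the
#' reference Lden is summarised (min, quartiles, mean, sd, max) and a
#' one-way ANOVA tests whether mean on-road levels differ between types.
#'
#' @param lden Reference [noise_raster] in dB(A).
#' @param roads A [road_network] on the same grid.
#' @return A list of class `road_type_summary`: `summary` tibble (one row
#'   per type present), `f_value`, `p_value`, `df` (ANOVA across types with
#'   at least two on-road cells).
#' @export
road_type_summary <- function(lden, roads) {
  groups <- list()
  for (ty in road_type_levels()) {
    pres <- rasterize_road_length(roads, lden, ty)$values > 0
    vals <- lden$values[pres & !is.na(lden$values)]
    if (length(vals)) groups[[ty]] <- vals
  }
  summ <- purrr::imap(groups, function(v, ty) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    tibble::tibble(road_type = ty, n = length(v), min = min(v), q1 = q[1],
                   median = q[2], mean = mean(v),
                   sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                   q3 = q[3], max = max(v))
  })
  summ <- dplyr::bind_rows(summ)
  summ$road_type <- factor(summ$road_type, levels = road_type_levels())
  use <- names(groups)[vapply(groups, length, 0L) >= 2]
  if (length(use) < length(groups)) {
    warning("road type(s) with < 2 on-road cells excluded from ANOVA: ",
            paste(setdiff(names(groups), use), collapse = ", "), call. = FALSE)
  }
  f_value <- p_value <- NA_real_; df <- c(NA_real_, NA_real_)
  if (length(use) >= 2) {
    dat <- data.frame(
      lden = unlist(groups[use], use.names = FALSE),
      type = factor(rep(use, vapply(groups[use], length, 0L)))
    )
    a <- stats::anova(stats::lm(lden ~ type, data = dat))
    f_value <- a$`F value`[1]; p_value <- a$`Pr(>F)`[1]
    df <- a$Df
    if (a$`Sum Sq`[1] < 1e-12) { f_value <- 0; p_value <- 1 }  # degenerate: no between-group variance
  }
  structure(list(summary = summ, f_value = f_value, p_value = p_value, df = df),
            class = "road_type_summary")
}

#' @export
print.road_type_summary <- function(x, ...) {
  print(x$summary)
  if (!is.na(x$f_value))
    cat(sprintf("one-way ANOVA: F(%d, %d) = %.2f, p = %.3g\n",
                x$df[1], x$df[2], x$f_value, x$p_value))
  invisible(x)
}
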