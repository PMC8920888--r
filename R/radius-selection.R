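#' Select one moving-window radius per variable
#'
#' The a-priori scale screen: for each windowed variable (six road-length
#' variables, building TPI, terrain TPI, seven land-cover fractions), an
#' intercept-and-slope bivariate OLS of the sampled Lden on the variable is
#' fitted at every candidate radius, and the radius with the smallest
#' in-sample RMSE is kept (ties break towards the smaller radius).
#' Proximity columns carry no radius and pass through unchanged, so with
#' the canonical radii the reduced stack has 6 + 14 = 21 columns Note the
#' screen is deliberately univariate — multivariate selection would
#' re-introduce variability between sampling experiments.
#'
#' @param stack The candidate [build_feature_stack()] (all radii present).
#' @param samples A [draw_sample()] response (>= 10 samples).
#' @return A list of class `radius_selection`: `choices` (tibble `variable`,
#'   `radius`, `rmse`, `r2`, `chosen`, one row per variable x radius) and
#'   `stack` (the reduced `feature_stack`, proximity columns first, then
#'   the chosen column per variable in stack order).
#' @export
select_radii <- function(stack, samples) {
  if (nrow(samples) < 10) stop("need at least 10 samples for the radius screen",
                               call. = FALSE)
  X <- design_matrix(stack, samples$cell)
  y <- samples$lden
  windowed <- unique(stack$specs$variable[!is.na(stack$specs$radius)])
  rows <- list()
  chosen_cols <- character()
  for (v in windowed) {
    sp <- stack$specs[stack$specs$variable == v & !is.na(stack$specs$radius), ]
    fits <- purrr::map2_dfr(sp$name, sp$radius, function(nm, r) {
      x <- X[, nm]
      if (stats::sd(x) == 0) {
        warning(sprintf("zero-variance column %s skipped in radius screen", nm),
                call. = FALSE)
        return(tibble::tibble(variable = v, radius = r, rmse = NA_real_,
                              r2 = NA_real_))
      }
      fit <- stats::lm.fit(cbind(1, x), y)
      m <- model_metrics(y, y - fit$residuals)
      tibble::tibble(variable = v, radius = r, rmse = m$rmse, r2 = m$r2)
    })
    if (all(is.na(fits$rmse))) {
      warning("variable ", v, " has no usable radius; dropped", call. = FALSE)
      fits$chosen <- FALSE
      rows[[v]] <- fits
      next
    }
    best_rmse <- min(fits$rmse, na.rm = TRUE)
    # tie rule: the smallest radius attaining the minimum (ties include
    # differences at floating-point noise level)
    tied <- !is.na(fits$rmse) & fits$rmse <= best_rmse * (1 + 1e-10)
    best <- min(fits$radius[tied])
    fits$chosen <- !is.na(fits$rmse) & fits$radius == best
    rows[[v]] <- fits
    chosen_cols <- c(chosen_cols, sp$name[sp$radius == best])
  }
  choices <- dplyr::bind_rows(rows)
  prox <- stack$specs$name[is.na(stack$specs$radius)]
  reduced <- stack_subset(stack, c(prox, chosen_cols))
  structure(list(choices = choices, stack = reduced),
            class = "radius_selection")
}

#' @export
print.radius_selection <- function(x, ...) {
  ch <- dplyr::filter(x$choices, .data$chosen)
  cat(sprintf("<radius_selection> %d variables, reduced stack width %d\n",
              nrow(ch), ncol(x$stack$values)))
  print(ch[, c("variable", "radius", "rmse", "r2")], n = 15)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.radius_selection <- function(x, ...) x$choices
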