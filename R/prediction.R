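#' Deploy a fitted LUR model to the full grid
#'
#' Per-cell linear prediction from the stack columns, with no clipping —
#' a LUR trained on mid-range levels may legitimately extrapolate beyond
#' the training Lden range when deployed area-wide. Feature names must
#' match the model's features exactly and in order; missing cells
#' propagate.
#'
#' @param model A [fit_ols()] result.
#' @param stack A [feature_stack] whose column names contain the model's
#'   feature names.
#' @return A [noise_raster] of predicted Lden (dB(A)).
#' @export
predict_raster <- function(model, stack) {
  have <- stack$specs$name
  need <- model$feature_names
  if (!identical(intersect(need, have), need)) {
    stop("stack is missing model feature(s): ",
         paste(setdiff(need, have), collapse = ", "), call. = FALSE)
  }
  b <- model$coefficients$estimate
  pred <- b[1] + drop(stack$values[, need, drop = FALSE] %*% b[-1])
  pred[!stack$mask] <- NA_real_
  out <- stack$grid
  out$values <- matrix(pred, nrow(out$values), ncol(out$values))
  out$units <- "dB(A)"
  out
}

#' Residual analysis of an area-wide prediction
#'
#' Compares a predicted noise surface against the reference map:
#' residuals (predicted minus reference) summarised per 5-dB reference
#' bin (count, median, IQR), MAE overall and restricted to built-up cells
#' (building height > 0), and the share of built-up cells whose absolute
#' error is at most 2.5 dB(A) — the half-width of a strategic-map class.
#'
#' @param predicted,reference Aligned [noise_raster]s (dB(A)).
#' @param builtup_mask [noise_raster] where values > 0 mark built-up cells
#'   (e.g. the building-height layer); `NULL` for no built-up analysis.
#' @param bin_width Reference bin width in dB(A) (default 5).
#' @return A list of class `prediction_report` with `residual_bins`
#'   (tibble: `bin_lower`, `n`, `median`, `iqr`), `mae_overall`,
#'   `mae_builtup`, `share_within_2p5`.
#' @export
residual_analysis <- function(predicted, reference, builtup_mask = NULL,
                              bin_width = 5) {
  stop_if_misaligned(predicted, reference, "predicted/reference rasters")
  ok <- !is.na(predicted$values) & !is.na(reference$values)
  res <- (predicted$values - reference$values)[ok]
  ref <- reference$values[ok]
  bin <- floor(ref / bin_width) * bin_width
  bins <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin_lower = bin, res = res), .data$bin_lower),
    n = dplyr::n(), median = stats::median(.data$res),
    iqr = stats::IQR(.data$res), .groups = "drop"
  )
  mae_builtup <- share <- NA_real_
  if (!is.null(builtup_mask)) {
    stop_if_misaligned(predicted, builtup_mask, "predicted/built-up rasters")
    bu <- ok & !is.na(builtup_mask$values) & builtup_mask$values > 0
    if (any(bu)) {
      bres <- (predicted$values - reference$values)[bu]
      mae_builtup <- mean(abs(bres))
      share <- mean(abs(bres) <= 2.5)
    }
  }
  structure(list(residual_bins = bins, mae_overall = mean(abs(res)),
                 mae_builtup = mae_builtup, share_within_2p5 = share),
            class = "prediction_report")
}

#' Threshold exposure report
#'
#' Shares of the area below a noise threshold (default the 55 dB(A)
#' strategic mapping threshold, strict "below"), overall and within the
#' built-up mask, plus the threshold iso-contour extracted from the
#' prediction surface as polyline rings.
#'
#' @param predicted A [noise_raster] (dB(A)).
#' @param builtup_mask As in [residual_analysis()].
#' @param threshold dB(A) threshold (default 55).
#' @return A list of class `threshold_report`: `threshold`,
#'   `area_below_threshold`, `builtup_below_threshold` (fractions in
#'   [0, 1]), and `contours` (tibble `ring`, `x`, `y`; rings follow the
#'   marching-squares iso-lines of the surface at the threshold level,
#'   traversed in the order returned by the contourer).
#' @export
threshold_report <- function(predicted, builtup_mask = NULL, threshold = 55) {
  stopifnot(is.finite(threshold))
  v <- predicted$values
  ok <- !is.na(v)
  area_below <- mean(v[ok] < threshold)
  builtup_below <- NA_real_
  if (!is.null(builtup_mask)) {
    stop_if_misaligned(predicted, builtup_mask, "predicted/built-up rasters")
    bu <- ok & !is.na(builtup_mask$values) & builtup_mask$values > 0
    if (any(bu)) builtup_below <- mean(v[bu] < threshold)
  }
  cc <- cell_centers(predicted)
  # contourLines wants ascending coordinates; flip rows to south-up
  z <- t(v[rev(seq_len(nrow(v))), , drop = FALSE])
  z[is.na(z)] <- min(v[ok]) - 1
  cl <- grDevices::contourLines(x = cc$x, y = rev(cc$y), z = z,
                                levels = threshold)
  contours <- purrr::imap_dfr(cl, function(ring, i) {
    rx <- ring$x; ry <- ring$y  # grab before `ring` is shadowed by the column
    tibble::tibble(ring = i, x = rx, y = ry)
  })
  structure(list(threshold = threshold, area_below_threshold = area_below,
                 builtup_below_threshold = builtup_below, contours = contours),
            class = "threshold_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> MAE %.2f dB(A) overall, %.2f built-up; %.0f%% of built-up within +/-2.5 dB\n",
              x$mae_overall, x$mae_builtup, 100 * x$share_within_2p5))
  print(x$residual_bins, n = 6)
  invisible(x)
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("<threshold_report> %.0f dB(A): %.1f%% of area below, %.1f%% of built-up below; %d contour ring(s)\n",
              x$threshold, 100 * x$area_below_threshold,
              100 * x$builtup_below_threshold,
              if (nrow(x$contours)) max(x$contours$ring) else 0L))
  invisible(x)
}
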