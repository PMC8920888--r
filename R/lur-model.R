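#' Accuracy metrics of predicted noise levels
#'
#' The three accuracy measures used throughout: coefficient of
#' determination `R^2 = 1 - SSres/SStot`, adjusted
#' `R^2 = 1 - (1 - R^2)(n - 1)/(n - p - 1)`, `RMSE = sqrt(SSres / n)` and
#' `MAE = mean(|residual|)`.
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 2).
#' @param p Number of predictors (for adjusted R^2; default 0).
#' @return One-row tibble `r2`, `adj_r2`, `rmse`, `mae`. With zero total
#'   variance in `observed`, `r2`/`adj_r2` are `NA`.
#' @export
model_metrics <- function(observed, predicted, p = 0) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  res <- observed - predicted
  ss_res <- sum(res^2)
  ss_tot <- sum((observed - mean(observed))^2)
  n <- length(observed)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  adj <- if (!is.na(r2) && n - p - 1 > 0) 1 - (1 - r2) * (n - 1) / (n - p - 1)
         else NA_real_
  tibble::tibble(r2 = r2, adj_r2 = adj,
                 rmse = sqrt(ss_res / n), mae = mean(abs(res)))
}

#' Fit an ordinary-least-squares LUR model
#'
#' Fits Lden on the predictor columns by linear least squares with classical
#' coefficient inference (standard errors, t values, two-sided p values)
#' and attaches in-sample accuracy metrics. Zero-variance columns — routine
#' at small N when, say, no motorway cell was sampled — are dropped with a
#' warning and recorded in the fit; genuinely collinear columns are an
#' error naming the offenders.
#'
#' @param design Numeric matrix or data frame of predictors (samples x
#'   features, named columns).
#' @param y Response vector (dB(A)).
#' @return An object of class `lur_model`: `coefficients` (tibble `term`,
#'   `estimate`, `std_error`, `statistic`, `p_value`), `feature_names`,
#'   `dropped` (zero-variance columns), `n`, `metrics`
#'   ([model_metrics()] row), `fitted`, `residuals`.
#' @examples
#' x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' fit <- fit_ols(x, 2 + x %*% c(1, -1, 0.5) + rnorm(20, 0, 0.1))
#' tidy(fit)
#' glance(fit)
#' @export
fit_ols <- function(design, y) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[is.na(sds) | sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, !colnames(X) %in% dropped, drop = FALSE]
  }
  p <- ncol(X)
  if (length(y) <= p + 1)
    stop(sprintf("need more samples than coefficients: n = %d, p + 1 = %d",
                 length(y), p + 1), call. = FALSE)
  qx <- qr(cbind(`(Intercept)` = 1, X))
  if (qx$rank < p + 1) {
    keep <- qx$pivot[seq_len(qx$rank)]
    bad <- setdiff(colnames(X), colnames(X)[keep[-1] - 1L])
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(X)
  df$.y <- y
  fit <- stats::lm(.y ~ ., data = df)
  sm <- summary(fit)$coefficients
  coef_tbl <- tibble::tibble(
    term = rownames(sm), estimate = unname(sm[, 1]),
    std_error = unname(sm[, 2]), statistic = unname(sm[, 3]),
    p_value = unname(sm[, 4])
  )
  # lm mangles non-syntactic names; restore the originals
  coef_tbl$term <- c("(Intercept)", colnames(X))
  structure(
    list(coefficients = coef_tbl, feature_names = colnames(X),
         dropped = dropped, n = length(y),
         metrics = model_metrics(y, stats::fitted(fit), p = p),
         fitted = unname(stats::fitted(fit)),
         residuals = unname(stats::residuals(fit))),
    class = "lur_model"
  )
}

#' @export
print.lur_model <- function(x, ...) {
  cat(sprintf("<lur_model> n = %d, %d features (%d dropped)\n", x$n,
              length(x$feature_names), length(x$dropped)))
  m <- x$metrics
  cat(sprintf("  R2 = %.3f (adj %.3f), RMSE = %.2f, MAE = %.2f\n",
              m$r2, m$adj_r2, m$rmse, m$mae))
  print(x$coefficients, n = 8)
  invisible(x)
}

#' Tidy a fitted LUR model
#'
#' @param x A `lur_model`.
#' @param ... Unused.
#' @return `tidy()`: the coefficient tibble (`term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`); `glance()`: a one-row tibble
#'   with the fit metrics and `n`.
#' @exportS3Method generics::tidy
tidy.lur_model <- function(x, ...) x$coefficients

#' @rdname tidy.lur_model
#' @exportS3Method generics::glance
glance.lur_model <- function(x, ...) {
  dplyr::mutate(x$metrics, n = x$n, p = length(x$feature_names))
}

#' Predict from a fitted LUR model
#'
#' @param object A `lur_model`.
#' @param newdata Matrix or data frame containing (at least) the model's
#'   feature columns by name.
#' @param ... Unused.
#' @export
predict.lur_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  miss <- setdiff(object$feature_names, colnames(X))
  if (length(miss)) stop("newdata is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  b <- object$coefficients$estimate
  drop(b[1] + X[, object$feature_names, drop = FALSE] %*% b[-1])
}
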