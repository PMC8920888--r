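# internal: least-squares train/predict used inside CV folds. Aliased
# (rank-deficient) coefficients are treated as dropped; the affected columns
# are recorded on the result so fold logs stay honest.
fold_fit_predict <- function(Xtr, ytr, Xte) {
  fit <- stats::lm.fit(cbind(1, Xtr), ytr)
  b <- fit$coefficients
  aliased <- names(b)[is.na(b)]
  b[is.na(b)] <- 0
  list(pred = drop(cbind(1, Xte) %*% b), aliased = aliased)
}

#' Cross-validate a LUR model
#'
#' Evaluates model transferability under four complementary designs:
#' \describe{
#'   \item{loocv}{leave-one-out; summary metrics are computed from the
#'     pooled out-of-fold predictions (per-fold metrics are undefined for a
#'     single held-out point).}
#'   \item{lgocv}{repeated leave-group-out: in each of `repeats` folds a
#'     random `fraction` of the samples is held out; fold metrics are
#'     averaged into mean and sd.}
#'   \item{lsocv_admin, lsocv_landuse}{leave-structure-out, the spatially
#'     blocked variants: each zone label (admin district / settlement-
#'     structure class) is held out once, so the model must extrapolate
#'     into an unseen area. Folds whose training side would leave fewer
#'     observations than coefficients are skipped with a recorded reason.}
#' }
#'
#' @param samples A [draw_sample()] result.
#' @param stack A [build_feature_stack()] (or [select_radii()]-reduced)
#'   stack.
#' @param method One of `"loocv"`, `"lgocv"`, `"lsocv_admin"`,
#'   `"lsocv_landuse"`.
#' @param fraction Held-out fraction for `lgocv` (in (0, 1)).
#' @param repeats Number of lgocv repeats (default 20).
#' @param zones Label [noise_raster] from [rasterize_zones()] (required for
#'   the lsocv methods).
#' @param seed Integer seed for the lgocv partitions.
#' @return An object of class `lur_cv`: `method`, `param`, `folds` (tibble
#'   with per-fold n and held-out metrics), `predictions` (pooled
#'   out-of-fold predictions for loocv/lsocv), `summary` (one-row tibble:
#'   `r2`, `rmse`, `mae` means and sds across folds; for loocv the pooled
#'   `r2`), `pooled` ([model_metrics()] on pooled predictions where
#'   applicable).
#' @export
run_cv <- function(samples, stack, method = c("loocv", "lgocv", "lsocv_admin",
                                              "lsocv_landuse"),
                   fraction = NULL, repeats = 20, zones = NULL, seed = 1) {
  method <- match.arg(method)
  X <- design_matrix(stack, samples$cell)
  y <- samples$lden
  n <- length(y)
  sds <- apply(X, 2, stats::sd)
  X <- X[, !is.na(sds) & sds > 0, drop = FALSE]
  p <- ncol(X)
  set.seed(as.integer(seed))
  if (method == "loocv") {
    test_sets <- as.list(seq_len(n))
  } else if (method == "lgocv") {
    if (is.null(fraction) || fraction <= 0 || fraction >= 1)
      stop("lgocv needs a held-out fraction in (0, 1)", call. = FALSE)
    m <- max(1L, round(fraction * n))
    test_sets <- lapply(seq_len(repeats), function(i) sample(n, m))
  } else {
    if (is.null(zones)) stop(method, " requires a zone label raster",
                             call. = FALSE)
    lab <- as.vector(zones$values)[samples$cell]
    if (anyNA(lab)) {
      message(sum(is.na(lab)), " sample(s) outside any zone excluded from ",
              method)
    }
    test_sets <- split(which(!is.na(lab)), lab[!is.na(lab)])
  }
  folds <- list(); preds <- list(); skipped <- 0L
  for (f in seq_along(test_sets)) {
    te <- test_sets[[f]]
    tr <- setdiff(seq_len(n), te)
    if (length(tr) <= p + 1) { skipped <- skipped + 1L; next }
    fp <- fold_fit_predict(X[tr, , drop = FALSE], y[tr], X[te, , drop = FALSE])
    met <- if (length(te) >= 2) model_metrics(y[te], fp$pred)
           else tibble::tibble(r2 = NA_real_, adj_r2 = NA_real_,
                               rmse = abs(y[te] - fp$pred),
                               mae = abs(y[te] - fp$pred))
    folds[[length(folds) + 1L]] <- dplyr::mutate(
      met[, c("r2", "rmse", "mae")], fold = f, n_train = length(tr),
      n_test = length(te), .before = 1)
    preds[[length(preds) + 1L]] <- tibble::tibble(
      index = te, observed = y[te], predicted = fp$pred, fold = f)
  }
  if (!length(folds)) stop("all CV folds were skipped (too few samples)",
                           call. = FALSE)
  if (skipped) message(skipped, " fold(s) skipped: too few training samples")
  folds <- dplyr::bind_rows(folds)
  predictions <- dplyr::bind_rows(preds)
  pooled <- NULL
  if (method %in% c("loocv", "lsocv_admin", "lsocv_landuse")) {
    pooled <- model_metrics(predictions$observed, predictions$predicted)
  }
  mean_or_na <- function(z) if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE)
  sd_or_na <- function(z) if (sum(!is.na(z)) < 2) NA_real_ else stats::sd(z, na.rm = TRUE)
  summary <- tibble::tibble(
    r2 = if (method == "loocv") pooled$r2 else mean_or_na(folds$r2),
    rmse = if (method == "loocv") pooled$rmse else mean_or_na(folds$rmse),
    mae = if (method == "loocv") pooled$mae else mean_or_na(folds$mae),
    r2_sd = sd_or_na(folds$r2), rmse_sd = sd_or_na(folds$rmse),
    mae_sd = sd_or_na(folds$mae)
  )
  structure(list(method = method, param = fraction, folds = folds,
                 predictions = predictions, summary = summary,
                 pooled = pooled, skipped = skipped),
            class = "lur_cv")
}

#' @export
print.lur_cv <- function(x, ...) {
  cat(sprintf("<lur_cv> %s%s: %d folds%s\n", x$method,
              if (!is.null(x$param)) sprintf(" (%.0f%%)", 100 * x$param) else "",
              nrow(x$folds),
              if (x$skipped) sprintf(" (%d skipped)", x$skipped) else ""))
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lur_cv <- function(x, ...) x$folds

#' @exportS3Method generics::glance
glance.lur_cv <- function(x, ...) {
  dplyr::mutate(x$summary, method = x$method, .before = 1)
}

#' Model-robustness rule
#'
#' A fitted LUR counts as robust when the drop from the overall (all-sample)
#' R^2 to the cross-validated R^2 stays strictly below 0.15.
#'
#' @param overall_r2,cv_r2 Coefficients of determination.
#' @return `TRUE` iff `overall_r2 - cv_r2 < 0.15`.
#' @export
robustness_check <- function(overall_r2, cv_r2) {
  stopifnot(is.finite(overall_r2), is.finite(cv_r2))
  d <- overall_r2 - cv_r2
  # a difference representing exactly 0.15 must fail the strict rule even
  # when floating point lands a hair below it
  if (abs(d - 0.15) < 1e-10) return(FALSE)
  d < 0.15
}
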