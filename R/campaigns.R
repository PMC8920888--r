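#' Campaign design grid
#'
#' Expands the full virtual-field-campaign experiment design: one row per
#' (scheme, size, seed) triple. The reference study design — four schemes,
#' five sizes (50, 100, 200, 500, 1000) and 100 seeds — yields 2000
#' campaigns.
#'
#' @param schemes Character vector of sampling schemes.
#' @param sizes Integer vector of requested sample sizes.
#' @param seeds Integer vector of seeds (default `1:100`).
#' @return A tibble with columns `scheme`, `N_requested`, `seed`.
#' @export
campaign_grid <- function(schemes = c("random", "systematic",
                                      "stratified_landuse", "stratified_lden"),
                          sizes = c(50, 100, 200, 500, 1000),
                          seeds = 1:100) {
  stopifnot(length(schemes) > 0, length(sizes) > 0, length(seeds) > 0)
  tidyr::expand_grid(scheme = schemes, N_requested = as.integer(sizes),
                     seed = as.integer(seeds))
}

#' Run a grid of virtual field campaigns
#'
#' Executes every campaign of a design grid independently: draw the sample
#' under its scheme/size/seed, test its representativity against the
#' mapped population, fit the overall OLS model on the reduced feature
#' stack, and (optionally) run the requested cross-validations. Failed
#' fits are recorded with `failed = TRUE` and the error message, never
#' dropped. Records are independent, so execution order cannot affect the
#' result.
#'
#' @param lden Reference [noise_raster].
#' @param stack Reduced [feature_stack] (after [select_radii()]).
#' @param grid A [campaign_grid()] tibble (or arguments to build one via
#'   `schemes`, `sizes`, `seeds`).
#' @param schemes,sizes,seeds Used when `grid` is `NULL`.
#' @param cv_methods Character vector of [run_cv()] methods to evaluate per
#'   campaign (default none, the overall model only).
#' @param lgocv_fraction Fraction for `"lgocv"` if requested.
#' @param admin_zones,landuse_zones Label rasters for the lsocv methods and
#'   the `stratified_landuse` scheme.
#' @param strata_width dB(A) width of the `stratified_lden` strata.
#' @return A tibble of class `campaign_table`: one row per campaign with
#'   `scheme`, `N_requested`, `N_sampled`, `seed`, `sample_mean`,
#'   `sample_sd`, `t_test_p`, overall `r2`, `adj_r2`, `rmse`, `mae`,
#'   `failed`, `note`, and one `<method>_r2` / `<method>_rmse` /
#'   `<method>_mae` column triple per requested CV method.
#' @export
run_campaign_grid <- function(lden, stack, grid = NULL, schemes = "random",
                              sizes = 500, seeds = 1:20, cv_methods = character(),
                              lgocv_fraction = 0.25, admin_zones = NULL,
                              landuse_zones = NULL, strata_width = 5) {
  if (is.null(grid)) grid <- campaign_grid(schemes, sizes, seeds)
  strata_lden <- lden_strata(lden, strata_width)
  one <- function(scheme, N_requested, seed) {
    rec <- tibble::tibble(
      scheme = scheme, N_requested = N_requested, N_sampled = NA_integer_,
      seed = seed, sample_mean = NA_real_, sample_sd = NA_real_,
      t_test_p = NA_real_, r2 = NA_real_, adj_r2 = NA_real_, rmse = NA_real_,
      mae = NA_real_, failed = FALSE, note = NA_character_)
    for (m in cv_methods) {
      rec[[paste0(m, "_r2")]] <- NA_real_
      rec[[paste0(m, "_rmse")]] <- NA_real_
      rec[[paste0(m, "_mae")]] <- NA_real_
    }
    tryCatch({
      strata <- switch(scheme, stratified_lden = strata_lden,
                       stratified_landuse = landuse_zones, NULL)
      smp <- draw_sample(lden, scheme, N_requested, seed, strata = strata)
      rep_t <- representativity_test(smp, lden)
      fit <- suppressWarnings(fit_ols(design_matrix(stack, smp$cell), smp$lden))
      rec$N_sampled <- attr(smp, "N_sampled")
      rec$sample_mean <- rep_t$sample_mean; rec$sample_sd <- rep_t$sample_sd
      rec$t_test_p <- rep_t$p_value
      rec$r2 <- fit$metrics$r2; rec$adj_r2 <- fit$metrics$adj_r2
      rec$rmse <- fit$metrics$rmse; rec$mae <- fit$metrics$mae
      for (m in cv_methods) {
        cv <- suppressMessages(run_cv(
          smp, stack, method = if (m == "lgocv") "lgocv" else m,
          fraction = if (m == "lgocv") lgocv_fraction else NULL,
          zones = switch(m, lsocv_admin = admin_zones,
                         lsocv_landuse = landuse_zones, NULL),
          seed = seed))
        rec[[paste0(m, "_r2")]] <- cv$summary$r2
        rec[[paste0(m, "_rmse")]] <- cv$summary$rmse
        rec[[paste0(m, "_mae")]] <- cv$summary$mae
      }
      rec
    }, error = function(e) {
      rec$failed <- TRUE
      rec$note <- conditionMessage(e)
      rec
    })
  }
  out <- purrr::pmap_dfr(grid, one)
  class(out) <- c("campaign_table", class(out))
  out
}

#' Summarise campaign accuracy by scheme and size
#'
#' Aggregates the campaign records into the accuracy distribution per
#' (scheme, N): mean, standard deviation and the 5% / 95% percentiles of
#' R^2, RMSE and MAE. Quantiles use linear interpolation between order
#' statistics; a single-record group reports `NA` standard deviations.
#'
#' @param records A [run_campaign_grid()] table.
#' @return A tibble of class `campaign_summary`, one row per scheme x size.
#' @export
aggregate_results <- function(records) {
  ok <- dplyr::filter(records, !.data$failed)
  q <- function(z, p) stats::quantile(z, p, na.rm = TRUE, names = FALSE, type = 7)
  out <- dplyr::summarise(
    dplyr::group_by(ok, .data$scheme, .data$N_requested),
    n_campaigns = dplyr::n(),
    dplyr::across(c("r2", "rmse", "mae"),
                  list(mean = ~mean(.x, na.rm = TRUE),
                       sd = ~if (sum(!is.na(.x)) < 2) NA_real_ else stats::sd(.x, na.rm = TRUE),
                       q05 = ~q(.x, 0.05), q95 = ~q(.x, 0.95))),
    .groups = "drop"
  )
  class(out) <- c("campaign_summary", class(out))
  out
}
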