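#' Noise-level strata
#'
#' Bins an Lden raster into fixed-width classes anchored at 0 dB(A):
#' `bin(v) = floor(v / width)`, left-closed right-open, so with the default
#' 5-dB width a value of 55.0 falls in [55, 60). These bins are the strata
#' of the `stratified_lden` sampling scheme.
#'
#' @param lden A [noise_raster] in dB(A).
#' @param width Stratum width in dB(A) (default 5).
#' @return A [noise_raster] of integer bin labels (`floor(v / width)`).
#' @export
lden_strata <- function(lden, width = 5) {
  stopifnot(width > 0)
  out <- lden
  out$values <- floor(lden$values / width)
  out$units <- sprintf("%g dB(A) bin", width)
  out
}

#' Lattice spacing of a systematic design
#'
#' The spacing of a square virtual-microphone lattice that places `N`
#' samples over the valid area: `sqrt(valid_area / N)`. For 1.05 million
#' 10-m cells (105 km^2) and N = 500 this is 458 m.
#'
#' @param n_valid Number of valid cells.
#' @param cell_size Cell edge length (m).
#' @param N Target sample count.
#' @return Spacing in metres.
#' @export
lattice_spacing <- function(n_valid, cell_size, N) {
  sqrt(n_valid * cell_size^2 / N)
}

#' Draw a virtual-microphone sample
#'
#' Draws `N` cells from the valid cells of a reference Lden raster under one
#' of four schemes:
#' \describe{
#'   \item{random}{uniform without replacement.}
#'   \item{systematic}{a square lattice with spacing `sqrt(valid_area / N)`;
#'     the seed sets a deterministic offset of the lattice within one
#'     spacing, and lattice points snap to the valid cell containing them.
#'     If the lattice lands on more than `N` valid cells, a seeded uniform
#'     subsample trims the draw to `N`.}
#'   \item{stratified_lden, stratified_landuse}{equal allocation
#'     `floor(N / K)` per non-empty stratum, remainder spread over the
#'     largest strata, uniform without replacement within stratum. Strata
#'     smaller than their quota contribute all their cells, so the realised
#'     `N_sampled` can fall short of `N`.}
#' }
#'
#' @param lden Reference [noise_raster] (dB(A)); its non-missing cells are
#'   the population.
#' @param scheme One of `"random"`, `"systematic"`, `"stratified_lden"`,
#'   `"stratified_landuse"`.
#' @param N Requested sample size (>= 1, at most the population size).
#' @param seed Integer seed; identical `(scheme, N, seed)` reproduce the
#'   identical draw.
#' @param strata Integer-label [noise_raster] (required for the stratified
#'   schemes; ignored otherwise). For `stratified_lden` pass
#'   [lden_strata()], for `stratified_landuse` a [rasterize_zones()] label
#'   raster.
#' @return A tibble of class `sample_set` with columns `row`, `col`, `cell`,
#'   `x`, `y`, `lden`, `stratum`, and attributes `scheme`, `N_requested`,
#'   `N_sampled`, `seed`.
#' @export
draw_sample <- function(lden, scheme = c("random", "systematic",
                                         "stratified_lden",
                                         "stratified_landuse"),
                        N, seed, strata = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(N >= 1)
  v <- as.vector(lden$values)
  valid <- which(!is.na(v))
  if (N > length(valid))
    stop(sprintf("N = %d exceeds the %d valid cells", N, length(valid)),
         call. = FALSE)
  stratified <- scheme %in% c("stratified_lden", "stratified_landuse")
  if (stratified && is.null(strata))
    stop("stratified schemes require a strata raster", call. = FALSE)
  set.seed(as.integer(seed))
  nr <- nrow(lden$values); nc <- ncol(lden$values)

  if (scheme == "random") {
    cells <- sample(valid, N)
  } else if (scheme == "systematic") {
    s <- lattice_spacing(length(valid), lden$cell_size, N)
    off <- stats::runif(2, 0, s)
    xs <- seq(lden$origin_x + off[1], lden$origin_x + nc * lden$cell_size, by = s)
    ys <- seq(lden$origin_y - off[2], lden$origin_y - nr * lden$cell_size, by = -s)
    col <- floor((rep(xs, times = length(ys)) - lden$origin_x) / lden$cell_size) + 1L
    row <- floor((lden$origin_y - rep(ys, each = length(xs))) / lden$cell_size) + 1L
    ok <- col >= 1L & col <= nc & row >= 1L & row <= nr
    cells <- unique((col[ok] - 1L) * nr + row[ok])
    cells <- cells[!is.na(v[cells])]
    if (length(cells) > N) cells <- sort(sample(cells, N))
  } else {
    sv <- as.vector(strata$values)
    if (length(sv) != length(v))
      stop("strata raster does not match the Lden grid", call. = FALSE)
    labs <- sv[valid]
    keep <- !is.na(labs)
    if (!all(keep)) message(sum(!keep), " valid cell(s) outside any stratum ignored")
    pool <- split(valid[keep], labs[keep])
    sizes <- lengths(pool)
    K <- length(pool)
    alloc <- rep(N %/% K, K)
    rem <- N - sum(alloc)
    if (rem > 0) {
      big <- order(sizes, decreasing = TRUE)[seq_len(rem)]
      alloc[big] <- alloc[big] + 1L
    }
    cells <- integer(0)
    for (k in seq_len(K)) {
      take <- min(alloc[k], sizes[k])
      cells <- c(cells,
                 if (take == sizes[k]) pool[[k]]
                 else sample(pool[[k]], take))
    }
  }
  cells <- as.integer(cells)
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  strat_at <- if (!is.null(strata)) as.vector(strata$values)[cells]
              else rep(NA_real_, length(cells))
  out <- tibble::tibble(
    row = row, col = col, cell = cells,
    x = lden$origin_x + (col - 0.5) * lden$cell_size,
    y = lden$origin_y - (row - 0.5) * lden$cell_size,
    lden = v[cells], stratum = strat_at
  )
  attr(out, "scheme") <- scheme
  attr(out, "N_requested") <- as.integer(N)
  attr(out, "N_sampled") <- nrow(out)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("sample_set", class(out))
  out
}

#' Representativity t-test of a sample
#'
#' Compares the virtual-microphone sample against the full valid-cell
#' population with a pooled-variance two-sided two-sample t-test (the
#' sample is compared to the total population, not population minus
#' sample). A high p value means the campaign represents the mapped noise.
#'
#' @param sample A [draw_sample()] result (needs >= 2 samples).
#' @param population The reference [noise_raster].
#' @return A one-row tibble: `sample_mean`, `sample_sd`, `pop_mean`,
#'   `pop_sd`, `t`, `df`, `p_value`.
#' @export
representativity_test <- function(sample, population) {
  x <- sample$lden
  y <- as.vector(population$values)
  y <- y[!is.na(y)]
  stopifnot(length(x) >= 2)
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) {
    p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    message("zero pooled variance; degenerate p = ", p)
    tt <- list(statistic = c(t = if (p == 1) 0 else Inf),
               parameter = c(df = length(x) + length(y) - 2), p.value = p)
  } else {
    tt <- stats::t.test(x, y, var.equal = TRUE)
  }
  tibble::tibble(
    sample_mean = mean(x), sample_sd = stats::sd(x),
    pop_mean = mean(y), pop_sd = stats::sd(y),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value
  )
}
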