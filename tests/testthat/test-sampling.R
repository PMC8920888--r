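test_that("noise strata are left-closed 5-dB bins anchored at zero", {
  r <- noise_raster(matrix(c(51, 55, 54.999, 12.8, 88.3, 0), 2, 3))
  b <- lden_strata(r)$values
  expect_equal(b[1, 1], 10)  # 51 -> [50, 55)
  expect_equal(b[2, 1], 11)  # 55 -> [55, 60), left-closed
  expect_equal(b[1, 2], 10)
  expect_equal(b[2, 2], 2)   # 12.8 -> [10, 15)
  expect_equal(b[1, 3], 17)  # 88.3 -> [85, 90)
  # a raster spanning 12.8..88.3 can populate bins 2..17: 16 bins
  expect_equal(length(seq(2, 17)), 16)
})

test_that("systematic lattice spacing reproduces the 458-m design figure", {
  # 105 km^2 at 10-m cells = 1.05 million cells; N = 500
  expect_equal(lattice_spacing(1.05e6, 10, 500), sqrt(105e6 / 500))
  expect_equal(round(lattice_spacing(1.05e6, 10, 500)), 458)
})

test_that("draws are reproducible and honour the population", {
  fx <- small_fixture()
  a <- draw_sample(fx$lden, "random", 100, seed = 5)
  b <- draw_sample(fx$lden, "random", 100, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$cell, draw_sample(fx$lden, "random", 100, 6)$cell))
  expect_equal(anyDuplicated(a$cell), 0)
  expect_equal(a$lden, fx$lden$values[cbind(a$row, a$col)])
  # N = population -> the entire population, any seed
  pop <- sum(!is.na(fx$lden$values))
  full <- draw_sample(fx$lden, "random", pop, seed = 1)
  expect_equal(sort(full$cell), which(!is.na(as.vector(fx$lden$values))))
  expect_error(draw_sample(fx$lden, "random", pop + 1, 1), "exceeds")
})

test_that("systematic draws form a lattice with the design spacing", {
  fx <- small_fixture()
  s <- lattice_spacing(sum(!is.na(fx$lden$values)), 10, 50)
  smp <- draw_sample(fx$lden, "systematic", 50, seed = 2)
  expect_lte(nrow(smp), 50)
  d <- as.matrix(stats::dist(cbind(smp$x, smp$y)))
  diag(d) <- Inf
  expect_gte(min(d), s - 10 * sqrt(2))
  expect_identical(smp, draw_sample(fx$lden, "systematic", 50, seed = 2))
})

test_that("stratified draws take whole scarce strata and report N_sampled", {
  # population: 3 loud cells, the rest quiet
  v <- matrix(40, 10, 10); v[1, 1:3] <- 80
  r <- noise_raster(v, origin_y = 100)
  smp <- draw_sample(r, "stratified_lden", 20, seed = 3, strata = lden_strata(r))
  expect_true(all(which(as.vector(r$values) == 80) %in% smp$cell))
  expect_equal(attr(smp, "N_sampled"), nrow(smp))
  expect_lte(attr(smp, "N_sampled"), attr(smp, "N_requested"))
  # allocation 10 per stratum; loud stratum only has 3 -> N_sampled = 13
  expect_equal(nrow(smp), 13)
  expect_error(draw_sample(r, "stratified_lden", 10, 1), "require a strata")
})

test_that("equal allocation fills N when all strata are large enough", {
  fx <- small_fixture()
  lab <- rasterize_zones(fx$scene$landuse_zones, fx$scene$dem, by = "label")
  smp <- draw_sample(fx$lden, "stratified_landuse", 40, seed = 8, strata = lab)
  expect_equal(nrow(smp), 40)
  expect_true(all(table(smp$stratum) >= floor(40 / length(unique(smp$stratum)))))
})

test_that("random and systematic means are unbiased over repeated seeds", {
  fx <- small_fixture()
  popmean <- raster_mean(fx$lden)
  for (scheme in c("random", "systematic")) {
    means <- vapply(1:100, function(s)
      mean(draw_sample(fx$lden, scheme, 64, seed = s)$lden), 0)
    mc_se <- stats::sd(means) / sqrt(length(means))
    expect_lt(abs(mean(means) - popmean), 3 * mc_se + 1e-9)
  }
})

test_that("lden-stratified draws oversample rare loud cells", {
  fx <- small_fixture()
  strata <- lden_strata(fx$lden)
  popmean <- raster_mean(fx$lden)
  means <- vapply(1:100, function(s)
    mean(draw_sample(fx$lden, "stratified_lden", 200, seed = s,
                     strata = strata)$lden), 0)
  expect_gte(mean(means > popmean), 0.95)
})

test_that("the pooled t-test matches hand arithmetic and its degenerate cases", {
  x <- c(1, 2, 3); y <- c(1, 2, 3, 4, 5)
  sp2 <- ((3 - 1) * stats::var(x) + (5 - 1) * stats::var(y)) / (3 + 5 - 2)
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 5))
  p_hand <- 2 * stats::pt(-abs(t_hand), 6)
  pop <- noise_raster(matrix(y, 1, 5))
  smp <- tibble::tibble(lden = x)
  out <- representativity_test(smp, pop)
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$df, 6)
  expect_equal(out$p_value, p_hand, tolerance = 1e-12)

  # sample identical in mean to a zero-variance population
  degen_pop <- flat_raster(5, 2, 2)
  expect_message(
    out2 <- representativity_test(tibble::tibble(lden = c(5, 5)), degen_pop),
    "degenerate")
  expect_equal(out2$p_value, 1)

  # strongly shifted sample
  fx <- small_fixture()
  shifted <- draw_sample(fx$lden, "random", 100, seed = 1)
  shifted$lden <- shifted$lden + 10 * stats::sd(fx$lden$values)
  expect_lt(representativity_test(shifted, fx$lden)$p_value, 1e-10)
})
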