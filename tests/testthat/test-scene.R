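test_that("scene generation is deterministic in the seed", {
  a <- generate_scene(3, 55, 55)
  b <- generate_scene(3, 55, 55)
  expect_identical(a, b)
  c2 <- generate_scene(4, 55, 55)
  expect_false(identical(a$roads$geometry, c2$roads$geometry))
})

test_that("scenes carry the full road hierarchy, land-cover set and zones", {
  sc <- generate_scene(11, 200, 200)
  expect_setequal(as.character(unique(sc$roads$road_type)), road_type_levels())
  expect_setequal(sort(unique(as.vector(sc$landcover$values))), 1:7)
  expect_gte(nrow(sc$admin_zones), 6)
  expect_gte(nrow(sc$landuse_zones), 4)
  expect_true(any(sc$roads$tunnel))
  expect_true(any(sc$building_height$values > 0))
  # zone labels cover (essentially) the whole grid
  lab <- rasterize_zones(sc$admin_zones, sc$dem)
  expect_gte(mean(!is.na(lab$values)), 0.95)
  # all rasters share geometry
  expect_identical(dim(sc$dem$values), dim(sc$landcover$values))
  expect_identical(dim(sc$dem$values), dim(sc$building_height$values))
})

test_that("grids below the 50-cell minimum are rejected", {
  expect_error(generate_scene(1, 40, 120), "too small")
})

test_that("energetic summation behaves like decibel addition", {
  expect_equal(energetic_sum(c(60, 60)), 60 + 10 * log10(2), tolerance = 1e-12)
  expect_equal(energetic_sum(70), 70)
  # monotone: adding any source never lowers the total
  expect_gt(energetic_sum(c(70, 30)), 70)
  # permutation invariant
  expect_equal(energetic_sum(c(55, 62, 48)), energetic_sum(c(48, 55, 62)))
})

test_that("a single point source reproduces its level at the reference distance", {
  # 4-m segment -> one source at its midpoint (6, 105); receiver centre (5, 105)
  sc <- mini_scene(one_road(cbind(c(6, 6), c(103, 107)), type = "residential"))
  prm <- pure_spreading()
  ld <- simulate_lden(sc, prm)
  expect_equal(ld$values[11, 1],
               prm$emission_by_type[["residential"]] +
                 10 * log10(prm$source_spacing),
               tolerance = 1e-9)
})

test_that("duplicating a source adds 3.01 dB and distance doubling removes 6.02 dB", {
  seg <- cbind(c(5, 5), c(103, 107))
  one <- mini_scene(one_road(seg, type = "tertiary"))
  two <- mini_scene(road_network(c("tertiary", "tertiary"), list(seg, seg)))
  prm <- pure_spreading()
  l1 <- simulate_lden(one, prm)$values
  l2 <- simulate_lden(two, prm)$values
  expect_equal(l2 - l1, matrix(10 * log10(2), 21, 21), tolerance = 1e-9)
  # receiver at 10 m vs 20 m from the source column
  expect_equal(l1[11, 2] - l1[11, 3], 20 * log10(2), tolerance = 1e-6)
})

test_that("levels decay monotonically with distance from a straight road", {
  road <- one_road(cbind(c(5, 5), c(0, 210)), type = "primary")
  ld <- simulate_lden(mini_scene(road), pure_spreading())
  transect <- ld$values[11, ]
  expect_true(all(diff(transect) < 0))
  # and the total is never below the loudest single contribution
  expect_true(all(ld$values >= max(acoustic_params()$emission_by_type["primary"]) +
                    10 * log10(10) - 20 * log10(2200) - 1))
})

test_that("tunnel segments are silent in the acoustic fixture", {
  seg <- cbind(c(5, 5), c(0, 210))
  open_road <- mini_scene(one_road(seg, type = "trunk"))
  with_tunnel <- mini_scene(road_network(c("trunk", "trunk"),
                                         list(seg, cbind(c(105, 105), c(0, 210))),
                                         tunnel = c(FALSE, TRUE)))
  expect_equal(simulate_lden(with_tunnel, pure_spreading())$values,
               simulate_lden(open_road, pure_spreading())$values)
})

test_that("on-road mean levels preserve the emission hierarchy", {
  # needs the full-size scene: on very small grids every road sits inside
  # every other road's near field and the per-type means blur together
  fx <- campaign_fixture()
  rs <- road_type_summary(fx$lden, fx$scene$roads)
  summ <- rs$summary[order(match(rs$summary$road_type, road_type_levels())), ]
  expect_true(all(diff(summ$mean) < 0))
  expect_lt(rs$p_value, 0.001)
})

test_that("building shielding penalises blocked paths", {
  sc <- mini_scene(one_road(cbind(c(5, 5), c(0, 210)), type = "primary"))
  sc$building_height$values[11, 5] <- 20  # a slab between road and east side
  open_p <- pure_spreading()
  shield <- pure_spreading(shielding_db = 10)
  l_open <- simulate_lden(sc, open_p)$values
  l_shld <- simulate_lden(sc, shield)$values
  expect_equal(l_shld[11, 2], l_open[11, 2], tolerance = 1e-9)  # in front
  expect_lt(l_shld[11, 9], l_open[11, 9])                      # behind the slab
})

test_that("road-type ANOVA distinguishes separated groups and degenerates to F = 0", {
  g <- noise_raster(matrix(0, 10, 10), origin_y = 100)
  rn <- road_network(c("motorway", "residential"),
                     list(cbind(c(0, 100), c(95, 95)), cbind(c(0, 100), c(5, 5))))
  loud <- g; loud$values[1, ] <- 80 + stats::rnorm(10, 0, 0.1)
  loud$values[10, ] <- 50 + stats::rnorm(10, 0, 0.1)
  rs <- road_type_summary(loud, rn)
  expect_lt(rs$p_value, 0.001)
  flat <- g; flat$values[] <- 60
  rs0 <- road_type_summary(flat, rn)
  expect_equal(rs0$f_value, 0)
})

test_that("one-way ANOVA F matches hand-computed sums of squares on a toy", {
  vals <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8))
  grand <- mean(unlist(vals))
  ssb <- sum(vapply(vals, function(v) length(v) * (mean(v) - grand)^2, 0))
  ssw <- sum(vapply(vals, function(v) sum((v - mean(v))^2), 0))
  f_hand <- (ssb / 2) / (ssw / 6)
  dat <- data.frame(y = unlist(vals), g = rep(names(vals), each = 3))
  a <- stats::anova(stats::lm(y ~ g, dat))
  expect_equal(a$`F value`[1], f_hand, tolerance = 1e-12)
})
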