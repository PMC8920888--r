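test_that("raster write/read round trip preserves values and metadata exactly", {
  set.seed(1)
  r <- noise_raster(matrix(rnorm(12 * 9), 12, 9), origin_x = 123.25,
                    origin_y = 1200, cell_size = 10, units = "dB(A)")
  r$values[3, 4] <- NA
  path <- withr::local_tempfile(fileext = ".asc")
  write_raster(r, path)
  r2 <- read_raster(path, expected_cell_size = 10, units = "dB(A)")
  expect_identical(r2$values, r$values)
  expect_identical(r2$origin_x, r$origin_x)
  expect_identical(r2$origin_y, r$origin_y)
  expect_identical(r2$cell_size, r$cell_size)
})

test_that("nodata cells are flagged and excluded from statistics", {
  r <- flat_raster(5, 4, 4)
  r$values[1, 1] <- NA
  path <- withr::local_tempfile(fileext = ".asc")
  write_raster(r, path)
  back <- read_raster(path)
  expect_true(is.na(back$values[1, 1]))
  expect_equal(raster_mean(back), 5)
})

test_that("unexpected cell size and missing georeference are hard errors", {
  r <- flat_raster(1, 5, 5, cell_size = 20)
  path <- withr::local_tempfile(fileext = ".asc")
  write_raster(r, path)
  expect_error(read_raster(path, expected_cell_size = 10), "20.*10|10.*20")
  bad <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "cellsize 10", "NODATA_value -9999",
               "1 2", "3 4", "5 6"), bad)
  expect_error(read_raster(bad), "georeference")
})

test_that("cell centres follow the top-left origin convention", {
  r <- noise_raster(matrix(0, 3, 4), origin_x = 100, origin_y = 530,
                    cell_size = 10)
  cc <- cell_centers(r)
  expect_equal(cc$x, c(105, 115, 125, 135))
  expect_equal(cc$y, c(525, 515, 505))
  tb <- as_tibble(r)
  expect_equal(nrow(tb), 12)
  expect_equal(tb$x[tb$row == 2 & tb$col == 3], 125)
  expect_equal(tb$y[tb$row == 2 & tb$col == 3], 515)
})

test_that("GeoJSON roads round trip and honour OSM-style properties", {
  rn <- road_network(c("motorway", "residential"),
                     list(cbind(c(0, 100), c(50, 50)), cbind(c(0, 0), c(0, 90))),
                     lanes = c(2L, 1L), tunnel = c(FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_roads(rn, path)
  back <- read_roads(path)
  expect_equal(as.character(back$road_type), c("motorway", "residential"))
  expect_equal(back$lanes, c(2L, 1L))
  expect_equal(back$tunnel, c(FALSE, TRUE))
  expect_equal(back$geometry[[1]], rn$geometry[[1]])
})

test_that("road reader defaults lanes to 1, drops unmapped types, warns on missing highway", {
  path <- withr::local_tempfile(fileext = ".geojson")
  feat <- function(props, coords) list(
    type = "Feature", properties = props,
    geometry = list(type = "LineString",
                    coordinates = lapply(seq_len(nrow(coords)),
                                         function(i) coords[i, ]))
  )
  gj <- list(type = "FeatureCollection", features = list(
    feat(list(highway = "trunk"), cbind(c(0, 10), c(0, 10))),
    feat(list(highway = "service", lanes = 2), cbind(c(0, 5), c(0, 5))),
    feat(list(name = "no-highway"), cbind(c(0, 5), c(5, 5))),
    feat(list(highway = "primary", tunnel = "yes"), cbind(c(1, 2), c(3, 4)))
  ))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  expect_warning(
    expect_message(rn <- read_roads(path), "1 feature.*dropped"),
    "without a highway"
  )
  expect_equal(nrow(rn), 2)
  expect_equal(rn$lanes, c(1L, 1L))
  expect_true(rn$tunnel[rn$road_type == "primary"])
})

test_that("zone sets round trip through GeoJSON and rasterize by cell centre", {
  zs <- zone_set(c("A", "B"),
                 list(rect_ring_test(0, 50, 0, 100), rect_ring_test(50, 100, 0, 100)),
                 label = c("west", "east"))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_zones(zs, path)
  back <- read_zones(path)
  expect_equal(back$zone_id, c("A", "B"))
  expect_equal(back$label, c("west", "east"))

  grid <- noise_raster(matrix(0, 10, 10), origin_x = 0, origin_y = 100)
  lab <- rasterize_zones(back, grid)
  expect_equal(sort(unique(as.vector(lab$values))), c(1, 2))
  expect_true(all(lab$values[, 1:5] == 1))
  expect_true(all(lab$values[, 6:10] == 2))
})

test_that("uncovered margins become nodata and overlaps are rejected", {
  grid <- noise_raster(matrix(0, 10, 10), origin_x = 0, origin_y = 100)
  zs <- zone_set("inner", list(rect_ring_test(20, 80, 20, 80)))
  lab <- rasterize_zones(zs, grid)
  expect_true(is.na(lab$values[1, 1]))
  expect_equal(sum(!is.na(lab$values)), 36)
  overlapping <- zone_set(c("a", "b"),
                          list(rect_ring_test(0, 60, 0, 100),
                               rect_ring_test(40, 100, 0, 100)))
  expect_error(rasterize_zones(overlapping, grid), "overlap")
})

test_that("zone labels partition the covered area", {
  fx <- small_fixture()
  lab <- rasterize_zones(fx$scene$admin_zones, fx$scene$dem)
  expect_true(all(!is.na(lab$values)))  # admin rectangles tile the scene
  expect_gte(length(unique(as.vector(lab$values))), 6)
})
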