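test_that("field maps validate geometry and labels", {
  fm <- square_map("peanut")
  expect_s3_class(fm, "field_map")
  expect_equal(nrow(fm$fields), 1)
  # bow-tie self-intersection is rejected
  bow <- cbind(c(0, 100, 0, 100), c(0, 100, 100, 0))
  expect_error(
    field_map(tibble::tibble(field_id = "b", crop = "corn",
                             polygon = list(bow)),
              HIVE_LAT, HIVE_LON, 2018, coords = "local"),
    "self-intersecting")
  expect_error(
    field_map(tibble::tibble(field_id = "x", crop = "wheat",
                             polygon = list(square_field(0, 0, 50))),
              HIVE_LAT, HIVE_LON, 2018, coords = "local"),
    "crop label")
  # overlap is a warning, resolved by file order
  expect_warning(
    field_map(tibble::tibble(field_id = c("a", "b"),
                             crop = c("corn", "cotton"),
                             polygon = list(square_field(0, 500, 300),
                                            square_field(100, 550, 300))),
              HIVE_LAT, HIVE_LON, 2018, coords = "local"),
    "overlap")
})

test_that("KML and GeoJSON round-trip to the same field map", {
  fm <- square_map(c("peanut", "corn"), cx = c(-600, 400), cy = c(800, -900),
                   half = c(300, 250))
  kml <- withr::local_tempfile(fileext = ".kml")
  gj <- withr::local_tempfile(fileext = ".geojson")
  write_fieldmap_kml(fm, kml)
  write_fieldmap_geojson(fm, gj)
  fm_k <- read_fieldmap(kml, HIVE_LAT, HIVE_LON, 2018)
  fm_g <- read_fieldmap(gj, HIVE_LAT, HIVE_LON, 2018)
  expect_equal(fm_k$fields$crop, fm$fields$crop)
  expect_equal(fm_g$fields$crop, fm$fields$crop)
  for (i in 1:2) {
    expect_equal(fm_k$fields$polygon[[i]], fm$fields$polygon[[i]],
                 tolerance = 0.01, ignore_attr = TRUE)
    expect_equal(fm_g$fields$polygon[[i]], fm_k$fields$polygon[[i]],
                 tolerance = 0.01, ignore_attr = TRUE)
  }
  # wrong year filters everything out
  expect_error(read_fieldmap(gj, HIVE_LAT, HIVE_LON, 1999), "no polygon features")
})

test_that("point assignment matches the ray-casting oracle", {
  set.seed(21)
  for (rep in 1:6) {
    fm <- random_landscape(n_fields = 5)
    px <- runif(800, -2000, 2000)
    py <- runif(800, -2000, 2000)
    got <- assign_points(px, py, fm)
    want <- vapply(seq_along(px), function(i) raycast_label(px[i], py[i], fm),
                   character(1))
    expect_identical(got, want)
  }
})

test_that("boundary points are inside; far points fall back to other", {
  fm <- square_map("peanut", cx = 0, cy = 1000, half = 500)
  expect_equal(assign_points(0, 1000, fm), "peanut") # centroid
  expect_equal(assign_points(500, 1000, fm), "peanut") # edge
  expect_equal(assign_points(500, 1500, fm), "peanut") # vertex
  expect_equal(assign_points(0, 10000, fm), "other")
  # region-of-interest handling
  expect_equal(assign_points(0, 1000, fm, max_radius_m = 500), "other")
  expect_true(is.na(assign_points(0, 1000, fm, max_radius_m = 500,
                                  beyond = "drop")))
})

test_that("land cover matches analytic areas and is order-invariant", {
  # 1 km x 1 km square wholly inside the 2 km disc
  fm <- square_map("peanut", cx = 0, cy = 1000, half = 500)
  cov <- land_cover_fraction(fm, 2000)
  expect_equal(cov$percent[cov$crop == "peanut"],
               100 * 1e6 / (pi * 2000^2), tolerance = 1e-4)
  expect_equal(sum(cov$percent), 100, tolerance = 1e-6)
  # empty map: everything is other
  fm0 <- field_map(tibble::tibble(field_id = character(), crop = character(),
                                  polygon = list()),
                   HIVE_LAT, HIVE_LON, 2018, coords = "local")
  cov0 <- land_cover_fraction(fm0, 2000)
  expect_equal(cov0$percent[cov0$crop == "other"], 100)
  # two disjoint equal squares: equal fractions, additive
  fm2 <- square_map(c("corn", "cotton"), cx = c(-800, 800), cy = c(0, 0),
                    half = c(250, 250))
  cov2 <- land_cover_fraction(fm2, 2000)
  expect_equal(cov2$percent[cov2$crop == "corn"],
               cov2$percent[cov2$crop == "cotton"], tolerance = 1e-9)
  # vertex-order reversal changes nothing
  fm2r <- fm2
  fm2r$fields$polygon <- lapply(fm2$fields$polygon,
                                function(p) p[rev(seq_len(nrow(p))), ])
  expect_equal(land_cover_fraction(fm2r, 2000), cov2)
  # partial overlap with the disc is clipped: half-plane sanity
  fmx <- square_map("soybean", cx = 2000, cy = 0, half = 300)
  covx <- land_cover_fraction(fmx, 2000)
  expect_lt(covx$percent[covx$crop == "soybean"],
            100 * 600 * 600 / (pi * 2000^2))
  expect_gt(covx$percent[covx$crop == "soybean"], 0)
})

test_that("grid binning conserves weight and splits dances over draws", {
  pts <- tibble::tibble(
    dance_id = rep(c("a", "b"), each = 3),
    east_m = c(10, 12, 14, 60, 61, 62),
    north_m = c(5, 6, 7, 80, 81, 82)
  )
  g <- grid_bin(pts, cell_m = 25)
  expect_equal(sum(g$percent), 100, tolerance = 1e-9)
  expect_equal(nrow(g), 2) # one cell per dance here
  expect_equal(g$percent, c(50, 50))
  # a dance fully in one cell puts all its weight there
  g1 <- grid_bin(pts[pts$dance_id == "a", ], cell_m = 25)
  expect_equal(g1$percent, 100)
  # cells are half-open and hive-anchored
  edge <- tibble::tibble(east_m = c(0, 24.999, 25), north_m = c(0, 0, 0))
  ge <- grid_bin(edge, cell_m = 25)
  expect_equal(ge$i, c(0, 1))
  expect_equal(ge$percent, c(200 / 3, 100 / 3), tolerance = 1e-9)
  # conservation under random clouds
  set.seed(4)
  rnd <- tibble::tibble(dance_id = rep(letters[1:10], each = 40),
                        east_m = rnorm(400, 0, 900),
                        north_m = rnorm(400, 0, 900))
  expect_equal(sum(grid_bin(rnd)$percent), 100, tolerance = 1e-9)
})

test_that("bloom periods use closed full-bloom intervals", {
  cal <- bloom_calendar(tibble::tibble(
    crop = "peanut", year = 2018,
    full_bloom_start = "2018-07-01", full_bloom_end = "2018-08-15"))
  expect_equal(as.character(bloom_period("2018-06-30", "peanut", 2018, cal)), "pre")
  expect_equal(as.character(bloom_period("2018-07-01", "peanut", 2018, cal)), "during")
  expect_equal(as.character(bloom_period("2018-08-15", "peanut", 2018, cal)), "during")
  expect_equal(as.character(bloom_period("2018-08-16", "peanut", 2018, cal)), "post")
  expect_error(bloom_period("2018-07-01", "corn", 2018, cal), "no entry")
  expect_error(bloom_calendar(tibble::tibble(
    crop = "x", year = 2018,
    full_bloom_start = "2018-08-01", full_bloom_end = "2018-07-01")),
    "precede")
  # YAML round trip
  path <- withr::local_tempfile(fileext = ".yaml")
  write_bloom_calendar(cal, path)
  cal2 <- read_bloom_calendar(path)
  expect_equal(cal2$full_bloom_start, cal$full_bloom_start)
})
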