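small_cfg <- function(...) {
  generator_config(n_dances = 150, years = 2018L, ...)
}

test_that("generated landscapes hit their land-cover targets", {
  cfg <- small_cfg()
  land <- generate_landscape(cfg, seed = 2)
  cov <- land_cover_fraction(land$fmap, 2000)
  for (i in seq_len(nrow(cfg$field_spec))) {
    crop <- cfg$field_spec$crop[[i]]
    expect_lt(abs(cov$percent[cov$crop == crop] -
                    cfg$field_spec$target_pct[[i]]), 1)
  }
  # determinism
  land2 <- generate_landscape(cfg, seed = 2)
  expect_equal(land2$fmap$fields, land$fmap$fields)
  # zero fields: everything is other
  cfg0 <- small_cfg(field_spec = tibble::tibble(
    crop = character(), target_pct = numeric(), n_fields = integer(),
    band_min_m = numeric(), band_max_m = numeric()))
  land0 <- generate_landscape(cfg0, seed = 1)
  cov0 <- land_cover_fraction(land0$fmap, 2000)
  expect_equal(cov0$percent[cov0$crop == "other"], 100)
})

test_that("category frequencies follow cover times attractiveness weight", {
  # equal weights: frequencies match land cover within binomial error
  cfg <- generator_config(
    n_dances = 1200, years = 2018L,
    attract_weights = tibble::tibble(crop = character(), month = integer(),
                                     weight = numeric()))
  land <- generate_landscape(cfg, seed = 3)
  truths <- generate_season(cfg, land$fmap, seed = 3)
  cov <- land_cover_fraction(land$fmap, 2000)
  for (crop in c("peanut", "soybean", "corn", "cotton")) {
    p <- cov$percent[cov$crop == crop] / 100
    obs <- mean(truths$true_crop == crop)
    expect_lt(abs(obs - p), 3.5 * sqrt(p * (1 - p) / 1200))
  }
  # crop points actually fall inside that crop's fields
  idx <- which(truths$true_crop == "peanut")
  lab <- assign_points(truths$true_east_m[idx], truths$true_north_m[idx],
                       land$fmap)
  expect_true(all(lab == "peanut"))

  # a 4x July weight multiplies the July odds by ~4
  cfg4 <- generator_config(
    n_dances = 3000, years = 2018L,
    attract_weights = tibble::tibble(crop = "peanut", month = 7L, weight = 4))
  land4 <- generate_landscape(cfg4, seed = 4)
  truths4 <- generate_season(cfg4, land4$fmap, seed = 4)
  cov4 <- land_cover_fraction(land4$fmap, 2000)
  p <- cov4$percent[cov4$crop == "peanut"]
  expected_july <- 4 * p / (100 + 3 * p) # renormalized categorical share
  obs_july <- mean(truths4$true_crop[truths4$month == 7] == "peanut")
  n_july <- sum(truths4$month == 7)
  expect_lt(abs(obs_july - expected_july),
            3.5 * sqrt(expected_july * (1 - expected_july) / n_july))

  # weights concentrated on one crop send every dance there
  cfgc <- small_cfg(attract_weights = tibble::tibble(
    crop = rep("corn", 7), month = 4:10, weight = rep(1e9, 7)))
  landc <- generate_landscape(cfgc, seed = 5)
  truthsc <- generate_season(cfgc, landc$fmap, seed = 5)
  expect_true(all(truthsc$true_crop == "corn"))
})

test_that("zero-noise generation round-trips through the decoder", {
  cfg <- small_cfg(run_duration_sd_s = 0, run_angle_sd_deg = 0,
                   cal = noiseless_cal())
  land <- generate_landscape(cfg, seed = 6)
  truths <- generate_season(cfg, land$fmap, seed = 6)
  runs <- generate_runs(truths, cfg, seed = 6)
  vecs <- decode_dances(runs, cfg$hive_lat, cfg$hive_lon, cfg$cal)
  vecs <- vecs[match(truths$dance_id, vecs$dance_id), ]
  berr <- abs(wrap_angle(vecs$bearing_deg - truths$true_bearing_deg))
  expect_lt(max(berr), 1e-6) # angles are not quantized
  # distance error bounded by half-frame quantization of each run
  derr <- abs(vecs$distance_m - truths$true_distance_m)
  expect_lt(max(derr), (0.5 / cfg$fps) / cfg$cal$slope_s_per_m + 1e-9)
})

test_that("run tables are reproducible and carry the decoding dialect", {
  cfg <- small_cfg()
  land <- generate_landscape(cfg, seed = 7)
  truths <- generate_season(cfg, land$fmap, seed = 7)
  r1 <- generate_runs(truths, cfg, seed = 7)
  r2 <- generate_runs(truths, cfg, seed = 7)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 4 * nrow(truths))
  # CSV round trip through the reader
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(r1, path, row.names = FALSE)
  back <- read_waggle_runs(path)
  expect_equal(nrow(back), nrow(r1))
  expect_true(all(sort(unique(back$turn_direction)) == c("left", "right")))
  # 2 left + 2 right per dance
  turns <- dplyr::count(r1, dance_id, turn_direction)
  expect_true(all(turns$n == 2))
})
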