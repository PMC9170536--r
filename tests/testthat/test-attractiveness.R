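make_vectors <- function(n, months = 4:10, year = 2018L) {
  tibble::tibble(
    dance_id = sprintf("%d_%04d", year, seq_len(n)),
    month = rep_len(months, n),
    year = year
  )
}

test_that("labelling takes one draw per dance with its own distance", {
  fm <- square_map("corn", cx = 0, cy = 1000, half = 500)
  vecs <- make_vectors(5)
  cl <- tibble::tibble(
    dance_id = rep(vecs$dance_id, each = 10), draw = rep(1:10, 5),
    east_m = 0, north_m = 1000, distance_m = 1000, bearing_deg = 0
  )
  lab <- label_dances(vecs, cl, fm, seed = 1)
  expect_equal(nrow(lab), 5)
  expect_true(all(lab$outcome == "corn"))
  expect_equal(lab$distance_km, rep(1, 5))
  # a cloud entirely outside any field is labelled other
  cl$north_m <- 6000
  expect_true(all(label_dances(vecs, cl, fm, seed = 1)$outcome == "other"))
})

test_that("label frequencies converge to the cloud's in-field fractions", {
  fm <- square_map("peanut", cx = 0, cy = 1000, half = 500)
  vecs <- make_vectors(1)
  # 30% of draws inside the peanut square
  cl <- tibble::tibble(
    dance_id = vecs$dance_id, draw = 1:200,
    east_m = c(rep(0, 60), rep(4000, 140)),
    north_m = c(rep(1000, 60), rep(4000, 140)),
    distance_m = 1000, bearing_deg = 0
  )
  hits <- vapply(1:400, function(s) {
    label_dances(vecs, cl, fm, seed = s)$outcome == "peanut"
  }, logical(1))
  expect_equal(mean(hits), 0.3, tolerance = 3 * sqrt(0.3 * 0.7 / 400))
})

test_that("a single-month design is rejected", {
  fm <- square_map("corn")
  vecs <- make_vectors(20, months = 7)
  cl <- tibble::tibble(dance_id = rep(vecs$dance_id, each = 5),
                       draw = rep(1:5, 20), east_m = 0, north_m = 1000,
                       distance_m = 1000, bearing_deg = 0)
  expect_error(fit_attractiveness(vecs, cl, fm, n_models = 5),
               "month")
})

test_that("distance correction: near fields are not spuriously attractive", {
  # crop A near, crop B far, foraging spatially uniform in the disc:
  # month odds ratios for both crops should have CIs covering 1
  cfg <- generator_config(
    n_dances = 800, years = 2018L,
    field_spec = tibble::tibble(
      crop = c("peanut", "corn"), target_pct = c(8, 8), n_fields = c(3L, 3L),
      band_min_m = c(300, 1200), band_max_m = c(700, 1700)),
    attract_weights = tibble::tibble(crop = character(), month = integer(),
                                     weight = numeric()),
    other_distance_model = "uniform", max_distance_m = 2400
  )
  land <- generate_landscape(cfg, seed = 30)
  truths <- generate_season(cfg, land$fmap, seed = 30)
  runs <- generate_runs(truths, cfg, seed = 30)
  vecs <- decode_dances(runs, cfg$hive_lat, cfg$hive_lon, cfg$cal)
  cl <- suppressMessages(simulate_clouds(vecs, cfg$cal, n_draws = 100, seed = 30))
  fit <- suppressMessages(
    fit_attractiveness(vecs, cl, land$fmap, n_models = 80, seed = 30))
  est <- tidy(fit) |> dplyr::filter(.data$term %in% month.abb)
  expect_gt(nrow(est), 0)
  covers <- est$lo <= 1 & est$hi >= 1
  expect_gt(mean(covers), 0.9)
})

test_that("run bookkeeping reports dropped and ridge-refit models", {
  fm <- square_map(c("peanut", "corn"), cx = c(-600, 600), cy = c(800, 800),
                   half = c(300, 300))
  set.seed(40)
  vecs <- make_vectors(60, months = c(4, 7))
  cl <- purrr::map(seq_len(60), function(i) {
    inside <- runif(30) < 0.4
    crop_x <- if (i %% 2) -600 else 600
    tibble::tibble(dance_id = vecs$dance_id[[i]], draw = 1:30,
                   east_m = ifelse(inside, crop_x, 0),
                   north_m = ifelse(inside, 800, 3000),
                   distance_m = 1000, bearing_deg = 0)
  }) |> dplyr::bind_rows()
  fit <- suppressMessages(fit_attractiveness(vecs, cl, fm, n_models = 25, seed = 2))
  g <- glance(fit)
  expect_equal(g$n_used + g$n_dropped, 25)
  expect_true(all(tidy(fit)$lo <= tidy(fit)$odds_ratio))
  expect_true(all(tidy(fit)$odds_ratio <= tidy(fit)$hi))
  # the reference month never appears as a term
  expect_false("Apr" %in% tidy(fit)$term)
})
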