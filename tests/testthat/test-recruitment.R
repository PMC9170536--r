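fm <- square_map("peanut", cx = 0, cy = 1000, half = 500)

# degenerate cloud helper: every draw at one point
point_cloud <- function(ids, east, north, n_draws = 20) {
  tibble::tibble(
    dance_id = rep(ids, each = n_draws),
    draw = rep(seq_len(n_draws), length(ids)),
    east_m = rep(east, each = n_draws),
    north_m = rep(north, each = n_draws)
  )
}

test_that("degenerate clouds give degenerate estimates", {
  cl <- point_cloud(c("a", "b", "c"), c(0, 10, -10), c(1000, 990, 1010))
  est <- percent_recruitment(cl, fm, "peanut", n_reps = 200, seed = 1)
  expect_equal(est$point_pct, 100)
  expect_equal(est$lo_pct, 100)
  expect_equal(est$hi_pct, 100)
  expect_equal(est$n_dances, 3L)
})

test_that("a half-in cloud at n = 1 dance gives a Bernoulli CI", {
  # 50% of draws inside, 50% far outside: per-rep percentages are 0 or 100
  cl <- tibble::tibble(
    dance_id = "a", draw = 1:400,
    east_m = c(rep(0, 200), rep(5000, 200)),
    north_m = c(rep(1000, 200), rep(5000, 200))
  )
  est <- percent_recruitment(cl, fm, "peanut", n_reps = 4000, seed = 2)
  expect_true(est$point_pct %in% c(0, 50, 100)) # median of a 0/100 coin
  expect_equal(est$lo_pct, 0)
  expect_equal(est$hi_pct, 100)
  expect_lt(abs(est$mean_pct - 50), 3 * 50 / sqrt(4000))
})

test_that("CI width follows the binomial approximation at p = 0.2", {
  set.seed(31)
  n_dances <- 100
  # each dance: 20% of draws inside the field
  cl <- purrr::map(seq_len(n_dances), function(i) {
    inside <- c(rep(TRUE, 10), rep(FALSE, 40))
    tibble::tibble(dance_id = sprintf("d%03d", i), draw = 1:50,
                   east_m = ifelse(inside, 0, 4000),
                   north_m = ifelse(inside, 1000, 4000))
  }) |> dplyr::bind_rows()
  est <- percent_recruitment(cl, fm, "peanut", n_reps = 4000, seed = 3)
  expect_lt(abs(est$point_pct - 20), 2.5)
  width_expected <- 2 * 1.96 * sqrt(0.2 * 0.8 / n_dances) * 100
  expect_lt(abs((est$hi_pct - est$lo_pct) - width_expected), 3)
})

test_that("a crop set and its complement sum to 100 under a shared seed", {
  set.seed(8)
  cl <- purrr::map(1:30, function(i) {
    tibble::tibble(dance_id = sprintf("d%02d", i), draw = 1:40,
                   east_m = runif(40, -1500, 1500),
                   north_m = runif(40, -1500, 1500))
  }) |> dplyr::bind_rows()
  e1 <- percent_recruitment(cl, fm, "peanut", n_reps = 500, seed = 7)
  e2 <- percent_recruitment(cl, fm, c("soybean", "corn", "cotton", "other"),
                            n_reps = 500, seed = 7)
  expect_equal(e1$point_pct + e2$point_pct, 100, tolerance = 1e-9)
  expect_equal(e1$mean_pct + e2$mean_pct, 100, tolerance = 1e-9)
  expect_equal(e1$lo_pct + e2$hi_pct, 100, tolerance = 1e-9)
})

test_that("CI width shrinks as the number of dances grows", {
  widths <- sapply(c(10, 100, 1000), function(n) {
    cl <- purrr::map(seq_len(n), function(i) {
      inside <- runif(20) < 0.3
      tibble::tibble(dance_id = sprintf("d%04d", i), draw = 1:20,
                     east_m = ifelse(inside, 0, 4000),
                     north_m = ifelse(inside, 1000, 4000))
    }) |> dplyr::bind_rows()
    est <- percent_recruitment(cl, fm, "peanut", n_reps = 600, seed = n)
    est$hi_pct - est$lo_pct
  })
  expect_true(all(diff(widths) < 0))
})

test_that("bloom stratification partitions the dances per crop calendar", {
  cal <- bloom_calendar(tibble::tibble(
    crop = "peanut", year = 2018,
    full_bloom_start = "2018-07-01", full_bloom_end = "2018-08-15"))
  vecs <- tibble::tibble(
    dance_id = c("a", "b", "c"),
    date = c("2018-06-01", "2018-07-20", "2018-09-01"),
    year = 2018L)
  cl <- point_cloud(c("a", "b", "c"), c(0, 0, 4000), c(1000, 1000, 4000))
  est <- recruitment_by_bloom(vecs, cl, fm, cal, "peanut", n_reps = 100, seed = 1)
  expect_equal(as.character(est$period), c("pre", "during", "post"))
  expect_equal(est$n_dances, c(1L, 1L, 1L))
  expect_equal(est$point_pct, c(100, 100, 0))
  # empty stratum is flagged undefined, not an error
  vecs2 <- vecs[1:2, ]
  cl2 <- cl[cl$dance_id != "c", ]
  est2 <- recruitment_by_bloom(vecs2, cl2, fm, cal, "peanut",
                               n_reps = 100, seed = 1)
  expect_true(est2$undefined[est2$period == "post"])
  expect_true(is.na(est2$point_pct[est2$period == "post"]))
})

test_that("empty inputs error", {
  expect_error(percent_recruitment(point_cloud(character(0), numeric(0),
                                               numeric(0)), fm, "peanut"),
               "empty")
})
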