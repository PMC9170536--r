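test_that("intra-dance SDs use sample SD and circular SD", {
  runs <- make_dance_runs("d1", rep(1, 4), rep(30, 4))
  sds <- intra_dance_sd(runs)
  expect_equal(sds$duration_sd_s, 0)
  expect_equal(sds$angle_sd_deg, 0)
  runs2 <- make_dance_runs("d2", c(1, 1, 2, 2), c(10, 10, 20, 20))
  sds2 <- intra_dance_sd(runs2)
  expect_equal(sds2$duration_sd_s, 0.5774, tolerance = 1e-3)
  # frame quantization makes durations exact multiples of 1/30 here
  expect_equal(sds2$duration_sd_s, sd(c(1, 1, 2, 2)))
  expect_error(intra_dance_sd(runs[1:3, ]), "exactly 4")
})

test_that("planted high-variability dances head the review lists", {
  set.seed(13)
  runs <- purrr::map(1:20, function(i) {
    noisy <- i <= 3
    make_dance_runs(sprintf("d%02d", i),
                    1 + rnorm(4, 0, if (noisy) 0.5 else 0.02),
                    20 + rnorm(4, 0, if (noisy) 60 else 2))
  }) |> dplyr::bind_rows()
  sds <- intra_dance_sd(runs)
  top_d <- top_k_review(sds, k = 3, component = "duration")
  top_a <- top_k_review(sds, k = 3, component = "angle")
  expect_setequal(top_d$dance_id, c("d01", "d02", "d03"))
  expect_setequal(top_a$dance_id, c("d01", "d02", "d03"))
})

test_that("ties break deterministically by dance id", {
  runs <- purrr::map(c("z", "a", "m"), function(id) {
    make_dance_runs(id, c(1, 1, 2, 2), c(10, 10, 20, 20))
  }) |> dplyr::bind_rows()
  top <- top_k_review(intra_dance_sd(runs), k = 3, component = "duration")
  expect_equal(top$dance_id, c("a", "m", "z"))
  expect_warning(top_k_review(intra_dance_sd(runs), k = 10), "only 3")
})

test_that("removing a dance below the list does not change the list", {
  set.seed(14)
  runs <- purrr::map(1:15, function(i) {
    make_dance_runs(sprintf("d%02d", i), 1 + rnorm(4, 0, 0.02 * i),
                    20 + rnorm(4, 0, 0.5 * i))
  }) |> dplyr::bind_rows()
  full <- top_k_review(intra_dance_sd(runs), k = 5, component = "duration")
  low_id <- setdiff(sprintf("d%02d", 1:15), full$dance_id)[[1]]
  pruned <- top_k_review(intra_dance_sd(runs[runs$dance_id != low_id, ]),
                         k = 5, component = "duration")
  expect_equal(pruned$dance_id, full$dance_id)
})

test_that("iterative review terminates with corrected/noisy-accepted flags", {
  set.seed(15)
  n <- 40
  clean_dur <- function() 1.2 + rnorm(4, 0, 0.03)
  clean_ang <- function() 35 + rnorm(4, 0, 3)
  bad_ids <- sprintf("d%02d", sample(n, 8))
  runs <- purrr::map(1:n, function(i) {
    id <- sprintf("d%02d", i)
    dur <- clean_dur(); ang <- clean_ang()
    if (id %in% bad_ids) dur[2] <- dur[2] + 3 # typo-like entry error
    make_dance_runs(id, dur, ang)
  }) |> dplyr::bind_rows()
  # the "reviewer" recognises and fixes each planted error once; a second
  # look at an already-corrected dance finds nothing further to fix
  corrected_once <- character()
  fixer <- function(dance_id, dance_runs) {
    if (!dance_id %in% bad_ids || dance_id %in% corrected_once) return(NULL)
    corrected_once <<- c(corrected_once, dance_id)
    make_dance_runs(dance_id, clean_dur(), clean_ang())
  }
  res <- qc_review_cycle(runs, fixer, k = 5)
  expect_equal(res$n_corrected, length(bad_ids))
  expect_true(all(res$report$flag %in% c("ok", "corrected", "noisy-accepted")))
  expect_gt(res$n_rounds, 1)
  # every planted error was queued and resolved
  expect_true(all(res$report$flag[res$report$dance_id %in% bad_ids] %in%
                    c("corrected", "noisy-accepted")))
  expect_equal(sort(corrected_once), sort(bad_ids))
})

test_that("correcting a dance can only move it down the next ranking", {
  set.seed(16)
  runs <- purrr::map(1:12, function(i) {
    make_dance_runs(sprintf("d%02d", i), 1 + rnorm(4, 0, 0.05 * i), rep(20, 4))
  }) |> dplyr::bind_rows()
  sds <- qc_rank(intra_dance_sd(runs))
  worst <- sds$dance_id[sds$rank_duration == 1]
  fixed <- dplyr::bind_rows(
    runs[runs$dance_id != worst, ],
    make_dance_runs(worst, rep(1.05, 4), rep(20, 4)))
  sds2 <- qc_rank(intra_dance_sd(fixed))
  expect_gt(sds2$rank_duration[sds2$dance_id == worst],
            sds$rank_duration[sds$dance_id == worst])
})
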