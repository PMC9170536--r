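#' Intra-dance variability of the two dance components
#'
#' The four runs of one dance should agree; unusually large spread in
#' either component is a flag for a data-entry error (or a legitimately
#' "noisy" dancer). Duration spread is the sample SD (n-1 denominator);
#' angular spread is the circular SD of the offset-corrected angles,
#' which equals the linear SD for the tight clusters typical of real
#' dances but stays finite under wraparound.
#'
#' @param runs run-level tibble (see [read_waggle_runs()]).
#' @return tibble `(dance_id, duration_sd_s, angle_sd_deg)`.
#' @export
intra_dance_sd <- function(runs) {
  runs <- validate_runs(as_tibble(runs))
  n_runs <- table(runs$dance_id)
  if (any(n_runs != 4)) {
    abort(sprintf("dance(s) without exactly 4 runs: %s",
                  paste(names(n_runs)[n_runs != 4], collapse = ", ")))
  }
  runs %>%
    mutate(duration_s = run_duration(.data$start_frame, .data$end_frame,
                                     .data$fps, .data$dance_id, .data$run_index)) %>%
    group_by(.data$dance_id) %>%
    summarise(
      duration_sd_s = sd(.data$duration_s),
      angle_sd_deg = circular_sd(
        wrap_angle(.data$angle_deg + .data$angle_offset_deg)),
      .groups = "drop"
    ) %>%
    arrange(.data$dance_id)
}

#' Rank dances by intra-dance variability
#'
#' @param sds tibble from [intra_dance_sd()].
#' @return the input with `rank_duration` and `rank_angle` columns (rank
#'   1 = most variable; ties broken by `dance_id` for determinism).
#' @export
qc_rank <- function(sds) {
  sds %>%
    mutate(
      rank_duration = rank_desc_stable(.data$duration_sd_s, .data$dance_id),
      rank_angle = rank_desc_stable(.data$angle_sd_deg, .data$dance_id)
    )
}

rank_desc_stable <- function(x, id) {
  ord <- order(-x, id)
  r <- integer(length(x))
  r[ord] <- seq_along(x)
  r
}

#' Highest-variability dances for review
#'
#' Returns the `k` dances with the largest intra-dance SD for one
#' component, the review queue of the validation workflow. If fewer than
#' `k` dances are available all are returned with a warning.
#'
#' @param sds tibble from [intra_dance_sd()].
#' @param k queue length.
#' @param component `"duration"` or `"angle"`.
#' @return tibble of the top-`k` dances, most variable first.
#' @export
top_k_review <- function(sds, k = 10, component = c("duration", "angle")) {
  component <- match.arg(component)
  ranked <- qc_rank(sds)
  col <- if (component == "duration") "rank_duration" else "rank_angle"
  if (nrow(ranked) < k) {
    warn(sprintf("only %d dance(s) available for a top-%d review list.",
                 nrow(ranked), k))
    k <- nrow(ranked)
  }
  ranked %>% arrange(.data[[col]]) %>% head(k)
}

#' Iterative validation of high-variability dances
#'
#' Emulates the review workflow applied to hand-decoded data: each round,
#' the `k` most variable dances per component are inspected; dances with
#' a recognisable entry error are corrected (re-decoded) and re-scored,
#' the rest are accepted as genuinely noisy dancers. Rounds repeat until
#' every queued dance is `noisy-accepted`.
#'
#' The human judgement is injected as `correct_fun(dance_id, runs)`,
#' which returns corrected run rows for that dance or `NULL` to accept it
#' as noisy. Dances accepted as noisy stay accepted in later rounds.
#'
#' @param runs run-level tibble.
#' @param correct_fun correction callback (see above). The default
#'   accepts everything as noisy, terminating after one round.
#' @param k review-queue length per component.
#' @param max_rounds safety bound on iterations.
#' @return list with the final `runs`, a `report` tibble
#'   `(dance_id, duration_sd_s, angle_sd_deg, flag, round_index)` and
#'   `n_rounds`, `n_corrected`.
#' @export
qc_review_cycle <- function(runs, correct_fun = function(dance_id, runs) NULL,
                            k = 10, max_rounds = 50) {
  runs <- as_tibble(runs)
  flags <- tibble(dance_id = unique(runs$dance_id),
                  flag = "ok", round_index = 0L)
  n_corrected <- 0L
  round <- 0L
  repeat {
    round <- round + 1L
    if (round > max_rounds) {
      warn("review did not settle within `max_rounds`; stopping.")
      break
    }
    sds <- intra_dance_sd(runs)
    queue <- unique(c(top_k_review(sds, k, "duration")$dance_id,
                      top_k_review(sds, k, "angle")$dance_id))
    accepted <- flags$dance_id[flags$flag == "noisy-accepted"]
    todo <- setdiff(queue, accepted)
    if (!length(todo)) break
    for (id in todo) {
      fixed <- correct_fun(id, runs[runs$dance_id == id, ])
      if (is.null(fixed)) {
        flags$flag[flags$dance_id == id] <- "noisy-accepted"
      } else {
        runs <- bind_rows(runs[runs$dance_id != id, ], as_tibble(fixed)) %>%
          arrange(.data$dance_id, .data$run_index)
        flags$flag[flags$dance_id == id] <- "corrected"
        n_corrected <- n_corrected + 1L
      }
      flags$round_index[flags$dance_id == id] <- round
    }
  }
  report <- left_join(intra_dance_sd(runs), flags, by = "dance_id")
  list(runs = runs, report = report, n_rounds = round,
       n_corrected = n_corrected)
}
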