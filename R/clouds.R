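#' Simulate each dance's advertised location as a probability cloud
#'
#' Dances are imprecise in both components, so a decoded vector is mapped
#' not as a point but as a cloud of plausible advertised locations. For
#' each draw the duration receives Gaussian noise (`duration_sd_s`) before
#' inversion through the calibration line, and the bearing receives
#' von Mises noise with circular SD `angle_sd_deg`. Draws whose noisy
#' duration falls below the calibration intercept are floored at the
#' minimum distance (count reported via a message), preserving the draw
#' count downstream resampling relies on.
#'
#' Reproducibility: one pipeline `seed` deterministically derives an
#' independent substream per dance, so per-dance clouds do not change when
#' other dances are added or removed.
#'
#' @param vectors tibble of decoded dances as from [decode_dances()]
#'   (needs `dance_id`, `mean_duration_s`, `bearing_deg`).
#' @param cal a [calibration_model()] carrying the two noise SDs.
#' @param n_draws simulated locations per dance.
#' @param seed integer pipeline seed.
#' @param hive_lat,hive_lon optional hive coordinates to add lat/lon per
#'   draw.
#' @return a tibble with one row per draw: `dance_id`, `draw`,
#'   `distance_m`, `bearing_deg`, `east_m`, `north_m` (+ `lat`, `lon`).
#' @export
simulate_clouds <- function(vectors, cal = calibration_model(),
                            n_draws = 1000, seed = 1,
                            hive_lat = NULL, hive_lon = NULL) {
  stopifnot(inherits(cal, "calibration_model"))
  if (n_draws < 1) abort("`n_draws` must be >= 1.")
  need <- c("dance_id", "mean_duration_s", "bearing_deg")
  if (!all(need %in% names(vectors))) {
    abort(sprintf("`vectors` must contain columns %s", paste(need, collapse = ", ")))
  }

  kappa <- if (cal$angle_sd_deg > 0) vm_kappa_from_sd(cal$angle_sd_deg) else Inf
  n_floored <- 0L

  streams <- string_stream(vectors$dance_id)
  sim_one <- function(i) {
    set.seed(derive_seed(seed, streams[[i]]))
    dur <- vectors$mean_duration_s[[i]] + rnorm(n_draws, 0, cal$duration_sd_s)
    dist_raw <- (dur - cal$intercept_s) / cal$slope_s_per_m
    n_floored <<- n_floored + sum(dist_raw < cal$min_distance_m)
    d <- pmax(cal$min_distance_m, dist_raw)
    b <- if (is.finite(kappa)) {
      wrap_bearing(rvonmises_deg(n_draws, vectors$bearing_deg[[i]], kappa))
    } else {
      rep(vectors$bearing_deg[[i]], n_draws)
    }
    tibble(
      dance_id = vectors$dance_id[[i]],
      draw = seq_len(n_draws),
      distance_m = d,
      bearing_deg = b
    )
  }

  clouds <- purrr::map(seq_len(nrow(vectors)), sim_one) %>% bind_rows()
  xy <- to_cartesian(clouds$distance_m, clouds$bearing_deg, hive_lat, hive_lon)
  clouds <- dplyr::bind_cols(clouds, xy)
  if (n_floored > 0) {
    inform(sprintf("%d simulated draw(s) floored at the minimum distance.", n_floored))
  }
  clouds
}
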