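#' Read a run-level waggle dance table
#'
#' One row per waggle run. Required columns: `dance_id`, `colony_id`,
#' `date` (ISO-8601), `time_local` ("HH:MM:SS"), `utc_offset` (hours),
#' `fps`, `angle_offset_deg`, `run_index`, `start_frame`, `end_frame`,
#' `angle_deg` (signed degrees from vertical, clockwise-positive, in
#' (-180, 180]), `turn_direction` ("left"/"right"). Rows with missing
#' values in measured fields are dropped with a message, and any dance
#' left with fewer than its full complement of runs is dropped too,
#' mirroring the screening applied to hand-entered decoding sheets.
#'
#' @param path CSV file path.
#' @return a tibble of runs.
#' @export
read_waggle_runs <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_runs(df)
}

required_run_cols <- c(
  "dance_id", "colony_id", "date", "time_local", "utc_offset", "fps",
  "angle_offset_deg", "run_index", "start_frame", "end_frame",
  "angle_deg", "turn_direction"
)

validate_runs <- function(df) {
  missing_cols <- setdiff(required_run_cols, names(df))
  if (length(missing_cols)) {
    abort(sprintf("runs table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  measured <- c("start_frame", "end_frame", "angle_deg", "turn_direction")
  ok <- complete.cases(df[measured])
  if (!all(ok)) {
    inform(sprintf("dropping %d run row(s) with missing values.", sum(!ok)))
    bad_dances <- unique(df$dance_id[!ok])
    df <- df[ok & !(df$dance_id %in% bad_dances), , drop = FALSE]
  }
  if (any(df$angle_deg <= -180 | df$angle_deg > 180)) {
    abort("`angle_deg` must lie in (-180, 180].")
  }
  df
}

#' Duration of a waggle run from its frame interval
#'
#' @param start_frame,end_frame video frame indices; `end_frame` must
#'   exceed `start_frame`.
#' @param fps frames per second of the recording (30 for the standard
#'   camera setting).
#' @param dance_id,run_index optional identifiers used in the error
#'   message for invalid intervals.
#' @return duration in seconds, `(end_frame - start_frame) / fps`.
#' @export
run_duration <- function(start_frame, end_frame, fps = 30,
                         dance_id = NULL, run_index = NULL) {
  bad <- end_frame <= start_frame
  if (any(bad)) {
    id <- if (!is.null(dance_id)) {
      paste0(" (dance ", paste(unique(dance_id[bad]), collapse = ", "),
             if (!is.null(run_index))
               paste0(", run ", paste(run_index[bad], collapse = ", ")), ")")
    } else ""
    abort(paste0("non-positive frame interval", id,
                 ": end_frame must exceed start_frame."))
  }
  if (any(fps <= 0)) abort("`fps` must be > 0.")
  (end_frame - start_frame) / fps
}

# circular mean of offset-corrected angles + arithmetic mean duration for
# the four runs of one dance
mean_components <- function(durations_s, angles_deg, angle_offset_deg = 0) {
  if (length(durations_s) != 4 || length(angles_deg) != 4) {
    abort("a dance must contribute exactly 4 waggle runs.")
  }
  list(
    mean_duration_s = mean(durations_s),
    mean_angle_deg = circular_mean(wrap_angle(angles_deg + angle_offset_deg))
  )
}

#' Decode run-level dance measurements into per-dance foraging vectors
#'
#' For each dance: average the four run durations (arithmetic mean) and
#' the four plumb-line-corrected run angles (circular mean); compute the
#' solar azimuth at the hive for the dance's timestamp; add azimuth and
#' mean angle to obtain the geographic bearing; and invert the mean
#' duration through the calibration line to obtain the communicated
#' distance.
#'
#' By protocol four mid-dance consecutive runs with two left and two
#' right turns are decoded per dance; a dance without exactly four runs
#' is an error, while an unbalanced left/right count only warns.
#'
#' @param runs run-level tibble as returned by [read_waggle_runs()].
#' @param hive_lat,hive_lon hive coordinates, decimal degrees.
#' @param cal a [calibration_model()].
#' @return a tibble with one row per dance: `dance_id`, `colony_id`,
#'   `date`, `time_local`, `utc_offset`, `year`, `month`,
#'   `mean_duration_s`, `mean_angle_deg`, `solar_azimuth_deg`,
#'   `bearing_deg`, `distance_m`.
#' @export
decode_dances <- function(runs, hive_lat, hive_lon, cal = calibration_model()) {
  runs <- validate_runs(as_tibble(runs))
  stopifnot(inherits(cal, "calibration_model"))

  n_runs <- table(runs$dance_id)
  if (any(n_runs != 4)) {
    abort(sprintf("dance(s) without exactly 4 runs: %s",
                  paste(names(n_runs)[n_runs != 4], collapse = ", ")))
  }

  runs <- runs %>%
    mutate(duration_s = run_duration(.data$start_frame, .data$end_frame,
                                     .data$fps, .data$dance_id, .data$run_index))

  turn_tab <- runs %>%
    group_by(.data$dance_id) %>%
    summarise(n_left = sum(.data$turn_direction == "left"), .groups = "drop")
  unbalanced <- turn_tab$dance_id[turn_tab$n_left != 2]
  if (length(unbalanced)) {
    warn(sprintf("%d dance(s) without the 2-left/2-right turn balance (e.g. %s).",
                 length(unbalanced), unbalanced[[1]]))
  }

  per_dance <- runs %>%
    group_by(.data$dance_id) %>%
    summarise(
      colony_id = .data$colony_id[[1]],
      date = .data$date[[1]],
      time_local = .data$time_local[[1]],
      utc_offset = .data$utc_offset[[1]],
      mean_duration_s = mean(.data$duration_s),
      mean_angle_deg = circular_mean(
        wrap_angle(.data$angle_deg + .data$angle_offset_deg)),
      .groups = "drop"
    )

  az <- solar_azimuth(hive_lat, hive_lon, per_dance$date,
                      per_dance$time_local, per_dance$utc_offset)
  dates <- as.Date(per_dance$date)

  per_dance %>%
    mutate(
      year = as.integer(format(dates, "%Y")),
      month = as.integer(format(dates, "%m")),
      solar_azimuth_deg = az,
      bearing_deg = bearing_from_angle(.data$mean_angle_deg, az),
      distance_m = invert_duration(.data$mean_duration_s, cal)
    ) %>%
    arrange(.data$dance_id)
}
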