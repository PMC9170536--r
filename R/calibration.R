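#' Duration-distance calibration model
#'
#' The published "universal calibration" relates waggle-run duration
#' (seconds) linearly to foraging distance (meters):
#' `duration = intercept_s + slope_s_per_m * distance`. Decoding inverts
#' this line; location simulation adds Gaussian noise to duration and
#' von Mises noise to bearing, the two error components every dance
#' carries.
#'
#' The defaults are round representative values of the published
#' calibration lineage and are meant to be overridden with the constants a
#' study actually uses (see [read_calibration()]).
#'
#' @param intercept_s intercept of the calibration line, seconds.
#' @param slope_s_per_m slope, seconds per meter; must be > 0.
#' @param duration_sd_s residual SD of duration at fixed distance, seconds.
#' @param angle_sd_deg SD of the angular (bearing) error, degrees.
#' @param min_distance_m floor applied when inverting durations shorter
#'   than the intercept, meters.
#' @return an object of class `calibration_model`.
#' @examples
#' cal <- calibration_model(0.2, 0.0012)
#' expected_duration(1000, cal)   # 1.4 s
#' invert_duration(1.4, cal)      # 1000 m
#' @export
calibration_model <- function(intercept_s = 0.30,
                              slope_s_per_m = 0.00135,
                              duration_sd_s = 0.15,
                              angle_sd_deg = 15,
                              min_distance_m = 0) {
  if (!is.numeric(slope_s_per_m) || slope_s_per_m <= 0) {
    abort("`slope_s_per_m` must be a positive number.")
  }
  if (duration_sd_s < 0 || angle_sd_deg < 0) {
    abort("noise standard deviations must be >= 0.")
  }
  structure(
    list(
      intercept_s = intercept_s,
      slope_s_per_m = slope_s_per_m,
      duration_sd_s = duration_sd_s,
      angle_sd_deg = angle_sd_deg,
      min_distance_m = min_distance_m
    ),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model>\n")
  cat(sprintf("  duration = %.4g s + %.4g s/m * distance\n",
              x$intercept_s, x$slope_s_per_m))
  cat(sprintf("  noise: duration SD %.3g s, angle SD %.3g deg; floor %g m\n",
              x$duration_sd_s, x$angle_sd_deg, x$min_distance_m))
  invisible(x)
}

#' Expected waggle-run duration for a distance
#'
#' @param distance_m distance(s) from the hive, meters, >= 0.
#' @param cal a [calibration_model()].
#' @return duration(s), seconds.
#' @export
expected_duration <- function(distance_m, cal) {
  stopifnot(inherits(cal, "calibration_model"))
  if (any(distance_m < 0)) abort("`distance_m` must be >= 0.")
  cal$intercept_s + cal$slope_s_per_m * distance_m
}

#' Invert a waggle-run duration to a distance
#'
#' Durations below the calibration intercept would map to negative
#' distances; they are floored at `cal$min_distance_m` with a warning.
#'
#' @param duration_s duration(s), seconds, > 0.
#' @param cal a [calibration_model()].
#' @param quiet suppress the sub-intercept warning.
#' @return distance(s), meters, >= `cal$min_distance_m`.
#' @export
invert_duration <- function(duration_s, cal, quiet = FALSE) {
  stopifnot(inherits(cal, "calibration_model"))
  d <- (duration_s - cal$intercept_s) / cal$slope_s_per_m
  below <- d < cal$min_distance_m
  if (any(below) && !quiet) {
    warn(sprintf("%d duration(s) below the calibration intercept floored at %g m.",
                 sum(below), cal$min_distance_m))
  }
  pmax(cal$min_distance_m, d)
}

#' Read / write a calibration model as YAML
#'
#' The YAML file carries the five calibration fields so that the constants
#' used by a study travel with its data. An annotated template with the
#' package defaults ships at
#' `system.file("extdata", "calibration.yaml", package = "waggledance")`.
#'
#' @param path file path.
#' @return `read_calibration()` returns a [calibration_model()];
#'   `write_calibration()` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("intercept_s", "slope_s_per_m")
  if (!all(need %in% names(y))) {
    abort(sprintf("calibration file '%s' must define %s",
                  path, paste(need, collapse = ", ")))
  }
  calibration_model(
    intercept_s = y$intercept_s,
    slope_s_per_m = y$slope_s_per_m,
    duration_sd_s = y$duration_sd_s %||% 0,
    angle_sd_deg = y$angle_sd_deg %||% 0,
    min_distance_m = y$min_distance_m %||% 0
  )
}

#' @rdname read_calibration
#' @param cal a [calibration_model()].
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_model"))
  yaml::write_yaml(unclass(cal), path)
  invisible(path)
}
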