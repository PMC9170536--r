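# Fixture builders: everything is constructed in code at test time.

HIVE_LAT <- 36.6851
HIVE_LON <- -76.7671

# run-level rows for one dance from target durations (s) and angles (deg)
make_dance_runs <- function(dance_id, durations_s, angles_deg,
                            fps = 30, angle_offset_deg = 0,
                            date = "2018-07-15", time_local = "10:30:00",
                            utc_offset = -4, colony_id = "A",
                            turns = c("left", "right", "left", "right")) {
  start <- cumsum(c(100, round(durations_s[-4] * fps) + 40))
  tibble::tibble(
    dance_id = dance_id, colony_id = colony_id, date = date,
    time_local = time_local, utc_offset = utc_offset, fps = fps,
    angle_offset_deg = angle_offset_deg, run_index = 1:4,
    start_frame = start,
    end_frame = start + round(durations_s * fps),
    angle_deg = angles_deg, turn_direction = turns
  )
}

# axis-aligned square field(s) in the hive-centered plane
square_field <- function(cx, cy, half) {
  cbind(east_m = c(cx - half, cx + half, cx + half, cx - half),
        north_m = c(cy - half, cy - half, cy + half, cy + half))
}

square_map <- function(crops = "peanut", cx = 0, cy = 1000, half = 500,
                       year = 2018) {
  n <- length(crops)
  field_map(
    tibble::tibble(
      field_id = paste0("f", seq_len(n)),
      crop = crops,
      polygon = purrr::map(seq_len(n),
                           ~ square_field(cx[[min(.x, length(cx))]],
                                          cy[[min(.x, length(cy))]],
                                          half[[min(.x, length(half))]]))
    ),
    HIVE_LAT, HIVE_LON, year, coords = "local"
  )
}

# random simple (convex) polygons for property tests
random_convex_poly <- function(cx, cy, r) {
  k <- sample(3:8, 1)
  th <- sort(runif(k, 0, 2 * pi))
  cbind(cx + r * runif(1, 0.5, 1) * cos(th), cy + r * runif(1, 0.5, 1) * sin(th))
}

random_landscape <- function(n_fields = 6, year = 2018) {
  crops <- sample(c("peanut", "soybean", "corn", "cotton"), n_fields, replace = TRUE)
  polys <- purrr::map(seq_len(n_fields), function(i) {
    random_convex_poly(runif(1, -1500, 1500), runif(1, -1500, 1500),
                       runif(1, 100, 450))
  })
  suppressWarnings(field_map(
    tibble::tibble(field_id = paste0("rf", seq_len(n_fields)),
                   crop = crops, polygon = polys),
    HIVE_LAT, HIVE_LON, year, coords = "local"
  ))
}

# degenerate-noise calibration for deterministic pipelines
noiseless_cal <- function() {
  calibration_model(duration_sd_s = 0, angle_sd_deg = 0)
}
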