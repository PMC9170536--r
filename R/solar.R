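## Solar position from the NOAA solar-calculator equations (Meeus-based).
## Accuracy is a few hundredths of a degree over 1900-2100, far inside the
## <= 0.5 degree tolerance that matters for dance bearings.

# Julian day from a POSIXct in UTC
julian_day <- function(utc) as.numeric(utc) / 86400 + 2440587.5

# core NOAA computation; utc is POSIXct (UTC); returns list of vectors
solar_position_utc <- function(lat, lon, utc) {
  jd <- julian_day(utc)
  jc <- (jd - 2451545) / 36525

  l0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  m  <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ec <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)

  mr <- deg2rad(m)
  ceq <- sin(mr) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * mr) * (0.019993 - 0.000101 * jc) +
    sin(3 * mr) * 0.000289
  true_long <- l0 + ceq
  omega <- deg2rad(125.04 - 1934.136 * jc)
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega)

  e0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  eps <- e0 + 0.00256 * cos(omega)

  decl <- asin(sin(deg2rad(eps)) * sin(deg2rad(app_long)))

  y <- tan(deg2rad(eps / 2))^2
  l0r <- deg2rad(l0)
  eqtime <- 4 * rad2deg(
    y * sin(2 * l0r) - 2 * ec * sin(mr) + 4 * ec * y * sin(mr) * cos(2 * l0r) -
      0.5 * y^2 * sin(4 * l0r) - 1.25 * ec^2 * sin(2 * mr)
  )

  mins_utc <- (jd + 0.5 - floor(jd + 0.5)) * 1440
  tst <- (mins_utc + eqtime + 4 * lon) %% 1440
  ha <- tst / 4 - 180
  ha[ha < -180] <- ha[ha < -180] + 360

  latr <- deg2rad(lat)
  har <- deg2rad(ha)
  cos_zen <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(har)
  cos_zen <- pmin(1, pmax(-1, cos_zen))
  zen <- acos(cos_zen)

  az_arg <- (sin(latr) * cos(zen) - sin(decl)) / (cos(latr) * sin(zen))
  az_arg <- pmin(1, pmax(-1, az_arg))
  az <- ifelse(ha > 0,
               (rad2deg(acos(az_arg)) + 180) %% 360,
               (540 - rad2deg(acos(az_arg))) %% 360)

  list(azimuth_deg = az, elevation_deg = 90 - rad2deg(zen))
}

# combine date / "HH:MM:SS" / utc_offset hours into a UTC POSIXct
local_to_utc <- function(date, time_local, utc_offset) {
  t <- as.POSIXct(paste(as.character(date), time_local),
                  tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  if (anyNA(t)) abort("could not parse date/time_local; expected ISO date and HH:MM:SS.")
  t - utc_offset * 3600
}

#' Solar azimuth at a site and time
#'
#' Azimuth of the sun measured clockwise from true north, the reference a
#' dancing bee's vertical-referenced angle must be added to in order to
#' obtain a geographic bearing. Times are local civil clock times with an
#' explicit UTC offset (hours, e.g. -4 for EDT); getting the offset wrong
#' by an hour rotates every bearing by roughly 15 degrees, which is why it
#' is a required argument.
#'
#' @param lat,lon site coordinates in decimal degrees (lon east-positive).
#' @param date calendar date (`Date` or ISO-8601 string), vectorized.
#' @param time_local local clock time "HH:MM:SS", vectorized.
#' @param utc_offset offset of local clock from UTC in hours, vectorized.
#' @return numeric vector of azimuths in `[0, 360)`. A warning is raised
#'   for instants when the sun is below the horizon (dances are filmed in
#'   daytime, so this indicates a timestamp or offset error).
#' @examples
#' solar_azimuth(36.685, -76.767, "2018-07-15", "10:30:00", -4)
#' @export
solar_azimuth <- function(lat, lon, date, time_local, utc_offset) {
  if (any(abs(lat) > 90)) abort("`lat` must be within [-90, 90].")
  utc <- local_to_utc(date, time_local, utc_offset)
  pos <- solar_position_utc(lat, lon, utc)
  if (any(pos$elevation_deg < 0)) {
    warn(sprintf("sun below the horizon for %d timestamp(s); check time/UTC offset.",
                 sum(pos$elevation_deg < 0)))
  }
  pos$azimuth_deg
}

#' Geographic bearing from a dance angle and the solar azimuth
#'
#' Bees dance relative to vertical but orient relative to the sun: an
#' angle of zero (straight up the comb) points at the sun's azimuth, and
#' clockwise dance angles add clockwise to it.
#'
#' @param mean_angle_deg dance angle(s) from vertical, degrees,
#'   clockwise-positive.
#' @param solar_azimuth_deg solar azimuth(s), degrees clockwise from true
#'   north.
#' @return bearing(s) in `[0, 360)`.
#' @export
bearing_from_angle <- function(mean_angle_deg, solar_azimuth_deg) {
  wrap_bearing(solar_azimuth_deg + mean_angle_deg)
}
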