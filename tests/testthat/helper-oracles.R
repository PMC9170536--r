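# Independent oracles, kept free of the package's own code paths.

# Michalsky (1988) solar-position algorithm (Astronomical Almanac
# approximations) -- a different published algorithm than the package's.
michalsky_azimuth <- function(lat, lon, utc) {
  rad <- pi / 180
  delta <- as.numeric(utc) / 86400 + 2440587.5 - 2451545.0
  hour <- (as.numeric(utc) %% 86400) / 3600
  mnlong <- (280.460 + 0.9856474 * delta) %% 360
  mnanom <- ((357.528 + 0.9856003 * delta) %% 360) * rad
  eclong <- ((mnlong + 1.915 * sin(mnanom) + 0.020 * sin(2 * mnanom)) %% 360) * rad
  oblqec <- (23.439 - 0.0000004 * delta) * rad
  ra <- atan2(cos(oblqec) * sin(eclong), cos(eclong))
  dec <- asin(sin(oblqec) * sin(eclong))
  gmst <- (6.697375 + 0.0657098242 * delta + hour) %% 24
  lmst <- ((gmst + lon / 15) %% 24) * 15 * rad
  ha <- lmst - ra
  ha <- ((ha + pi) %% (2 * pi)) - pi
  latr <- lat * rad
  el <- asin(sin(dec) * sin(latr) + cos(dec) * cos(latr) * cos(ha))
  az <- asin(-cos(dec) * sin(ha) / cos(el))
  crit <- sin(dec) - sin(el) * sin(latr)
  az <- ifelse(crit >= 0, ifelse(sin(az) < 0, az + 2 * pi, az), pi - az)
  (az / rad) %% 360
}

# brute-force even-odd ray casting (horizontal ray to +x), one point at a
# time; boundary handling irrelevant for the random points it is used on
raycast_inside <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly_y[i] > py) != (poly_y[j] > py)) {
      xint <- poly_x[i] + (py - poly_y[i]) / (poly_y[j] - poly_y[i]) *
        (poly_x[j] - poly_x[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# vectorized even-odd crossing count over all points for one polygon
raycast_inside_vec <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  crossings <- integer(length(px))
  j <- n
  for (i in seq_len(n)) {
    cond <- (poly_y[i] > py) != (poly_y[j] > py)
    xint <- poly_x[i] + (py - poly_y[i]) / (poly_y[j] - poly_y[i]) *
      (poly_x[j] - poly_x[i])
    crossings <- crossings + as.integer(cond & px < xint)
    j <- i
  }
  crossings %% 2L == 1L
}

raycast_label_vec <- function(px, py, fmap) {
  lab <- rep("other", length(px))
  open <- rep(TRUE, length(px))
  for (i in seq_len(nrow(fmap$fields))) {
    p <- fmap$fields$polygon[[i]]
    hit <- open & raycast_inside_vec(px, py, p[, 1], p[, 2])
    lab[hit] <- fmap$fields$crop[[i]]
    open[hit] <- FALSE
  }
  lab
}

# oracle labelling: first polygon (file order) containing the point
raycast_label <- function(px, py, fmap) {
  for (i in seq_len(nrow(fmap$fields))) {
    p <- fmap$fields$polygon[[i]]
    if (raycast_inside(px, py, p[, 1], p[, 2])) return(fmap$fields$crop[[i]])
  }
  "other"
}
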