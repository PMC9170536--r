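## Hive-centered planar geometry. Dance geometry is polar around the hive,
## so all spatial work happens in a local azimuthal-equidistant plane
## centered on the hive: east = d sin(b), north = d cos(b). Over the <= 10
## km scales bees forage at, the planar error is under a meter.

#' Convert distance/bearing to hive-centered coordinates and lat/lon
#'
#' @param distance_m distance(s) from the hive, meters, >= 0.
#' @param bearing_deg bearing(s) clockwise from true north, degrees.
#' @param hive_lat,hive_lon hive coordinates; if supplied, geographic
#'   coordinates of each point are added via a geodesic destination-point
#'   computation.
#' @return a tibble with `east_m`, `north_m` and, when the hive is given,
#'   `lat`, `lon`.
#' @examples
#' to_cartesian(1000, 0)    # 1 km due north
#' to_cartesian(500, 225)   # south-west
#' @export
to_cartesian <- function(distance_m, bearing_deg,
                         hive_lat = NULL, hive_lon = NULL) {
  if (any(distance_m < 0)) abort("`distance_m` must be >= 0.")
  b <- deg2rad(bearing_deg)
  out <- tibble(
    east_m = distance_m * sin(b),
    north_m = distance_m * cos(b)
  )
  if (!is.null(hive_lat) && !is.null(hive_lon)) {
    ll <- geosphere::destPoint(cbind(hive_lon, hive_lat),
                               wrap_bearing(bearing_deg), distance_m)
    out$lon <- ll[, 1]
    out$lat <- ll[, 2]
  }
  out
}

# inverse: lon/lat matrix -> hive-centered east/north (meters)
lonlat_to_local <- function(lon, lat, hive_lat, hive_lon) {
  p <- cbind(lon, lat)
  h <- cbind(hive_lon, hive_lat)
  d <- geosphere::distGeo(h, p)
  b <- geosphere::bearing(h, p)
  b[is.na(b)] <- 0 # point at the hive itself
  tibble(east_m = d * sin(deg2rad(b)), north_m = d * cos(deg2rad(b)))
}
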