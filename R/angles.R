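## Angular arithmetic helpers. All public angles are degrees; bearings are
## measured clockwise from true north in [0, 360), dance angles are signed
## degrees from vertical in (-180, 180].

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in (-180, 180].
#' @export
wrap_angle <- function(x) {
  out <- x %% 360
  out[out > 180] <- out[out > 180] - 360
  out
}

#' Wrap an angle into [0, 360)
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in [0, 360).
#' @export
wrap_bearing <- function(x) x %% 360

#' Circular mean of angles in degrees
#'
#' Mean direction of the unit vectors, mapped back to (-180, 180].
#' Identical to the arithmetic mean for tightly clustered angles but safe
#' under wraparound (e.g. angles straddling +/-180).
#'
#' @param x numeric vector of angles in degrees.
#' @return length-1 numeric, in (-180, 180]. NaN if the resultant is zero.
#' @export
circular_mean <- function(x) {
  s <- mean(sin(deg2rad(x)))
  c <- mean(cos(deg2rad(x)))
  if (sqrt(s^2 + c^2) < 1e-12) return(NaN)
  m <- rad2deg(atan2(s, c))
  # atan2 returns (-180, 180]; -180 maps to +180 by convention
  if (m <= -180) m <- m + 360
  m
}

#' Circular standard deviation of angles in degrees
#'
#' sqrt(-2 log R) where R is the mean resultant length, converted to
#' degrees. Agrees with the linear SD for tight clusters.
#'
#' @param x numeric vector of angles in degrees.
#' @return length-1 numeric, degrees, >= 0.
#' @export
circular_sd <- function(x) {
  s <- mean(sin(deg2rad(x)))
  c <- mean(cos(deg2rad(x)))
  r <- min(1, sqrt(s^2 + c^2))
  rad2deg(sqrt(-2 * log(max(r, .Machine$double.xmin))))
}

## -- von Mises machinery (no circular-statistics package is depended on) --

# mean resultant length A1(kappa) = I1(kappa)/I0(kappa), exp-scaled for
# numerical stability at large kappa
besselI_ratio <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# concentration parameter whose circular SD (degrees) equals sd_deg;
# for tight concentrations A1(kappa) ~ 1 - 1/(2 kappa), i.e. kappa ~ 1/sd^2
vm_kappa_from_sd <- function(sd_deg) {
  stopifnot(sd_deg > 0)
  sd_rad <- deg2rad(sd_deg)
  if (sd_rad < 0.01) return(1 / sd_rad^2)
  target_r <- exp(-sd_rad^2 / 2)
  f <- function(k) besselI_ratio(k) - target_r
  uniroot(f, interval = c(1e-8, 1e5), tol = 1e-10)$root
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution,
# mean direction mu_deg, concentration kappa; vectorized batch rejection.
rvonmises_deg <- function(n, mu_deg, kappa) {
  if (kappa < 1e-8) return(wrap_angle(rad2deg(runif(n, -pi, pi)) + mu_deg))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(64L, ceiling((n - length(out)) * 1.4))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    out <- c(out, (sign(u3 - 0.5) * acos(f))[ok])
  }
  wrap_angle(mu_deg + rad2deg(out[seq_len(n)]))
}

# deterministic substream seed derived from a pipeline seed; kept < 2^31
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647
}

# stable numeric stream id for a string (so per-dance substreams depend on
# the dance identity, not its row position)
string_stream <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}
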