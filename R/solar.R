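# Solar geometry and circadian phase assignment.
#
# Phases follow the usual telemetry conventions:
#   day      sun centre altitude > -0.833 deg (refraction + semidiameter,
#            i.e. standard sunrise/sunset)
#   twilight -18 < altitude <= -0.833 deg (dawn and dusk pooled: the period
#            between the beginning of astronomical twilight and sunrise, and
#            between sunset and the end of astronomical twilight)
#   night    altitude <= -18 deg
#
# Altitude comes from the truncated-Meeus ephemeris used by the NOAA solar
# calculator (declination/right ascension from the apparent ecliptic
# longitude, hour angle via Greenwich sidereal time).  Accuracy is a few
# hundredths of a degree over 1900-2100, i.e. well under a minute in
# rise/set times at temperate latitudes.

DAY_THRESHOLD_DEG <- -0.833
NIGHT_THRESHOLD_DEG <- -18

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Solar altitude of the sun centre
#'
#' @param t POSIXct (UTC), vectorized.
#' @param lat,lon position in decimal degrees.
#' @return altitude in degrees (geometric, no refraction term; the phase
#'   thresholds carry the refraction convention instead).
#' @export
solar_altitude <- function(t, lat, lon) {
  t <- parse_utc(t)
  jd <- as.numeric(t) / 86400 + 2440587.5
  T <- (jd - 2451545) / 36525

  L0 <- (280.46646 + T * (36000.76983 + T * 0.0003032)) %% 360
  M <- deg2rad(357.52911 + T * (35999.05029 - 0.0001537 * T))
  C <- sin(M) * (1.914602 - T * (0.004817 + 0.000014 * T)) +
    sin(2 * M) * (0.019993 - 0.000101 * T) +
    sin(3 * M) * 0.000289
  true_long <- L0 + C
  omega <- deg2rad(125.04 - 1934.136 * T)
  lambda <- deg2rad(true_long - 0.00569 - 0.00478 * sin(omega))

  eps0 <- 23 + (26 + (21.448 - T * (46.815 + T * (0.00059 - T * 0.001813))) / 60) / 60
  eps <- deg2rad(eps0 + 0.00256 * cos(omega))

  dec <- asin(sin(eps) * sin(lambda))
  ra <- atan2(cos(eps) * sin(lambda), cos(lambda))

  gmst <- (280.46061837 + 360.98564736629 * (jd - 2451545)) %% 360
  H <- deg2rad(gmst + lon) - ra

  phi <- deg2rad(lat)
  rad2deg(asin(sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(H)))
}

#' Circadian phase at an instant and position
#'
#' @inheritParams solar_altitude
#' @return character vector in `c("day", "twilight", "night")`.
#' @export
circadian_phase <- function(t, lat, lon) {
  alt <- solar_altitude(t, lat, lon)
  ifelse(alt > DAY_THRESHOLD_DEG, "day",
    ifelse(alt > NIGHT_THRESHOLD_DEG, "twilight", "night")
  )
}

# All instants in the UTC day `date` where the altitude crosses `threshold`,
# located on a 1-min scan and refined by root bracketing to < 0.5 s.
solar_crossings <- function(date, lat, lon, threshold) {
  t0 <- as.POSIXct(paste0(format(as.Date(date)), " 00:00:00"), tz = "UTC")
  grid <- t0 + seq(0, 86400, by = 60)
  f <- solar_altitude(grid, lat, lon) - threshold
  sgn <- sign(f)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  out <- vapply(idx, function(i) {
    uniroot(
      function(s) solar_altitude(t0 + s, lat, lon) - threshold,
      lower = (i - 1) * 60, upper = i * 60, tol = 0.1
    )$root
  }, numeric(1))
  # exact grid hits (rare) count as crossings too
  out <- sort(unique(c(out, 60 * (which(f == 0) - 1))))
  t0 + out
}

#' Daily circadian phase durations
#'
#' Durations (hours) of day, twilight and night over one UTC calendar day at
#' a position, computed from the threshold-crossing times of the solar
#' altitude.  The three durations always sum to 24 h.  At ~51 deg N around
#' the June solstice the sun never reaches -18 deg, so night duration is 0
#' and twilight absorbs the whole dark period (a duration-zero convention,
#' not an error).
#'
#' @param date a `Date` (or coercible), interpreted as a UTC day.
#' @param lat,lon position in decimal degrees.
#' @return data.frame with columns `date`, `lat`, `lon`, `day_h`,
#'   `twilight_h`, `night_h`.
#' @export
phase_durations <- function(date, lat, lon) {
  date <- as.Date(date)
  lat <- rep_len(lat, length(date))
  lon <- rep_len(lon, length(date))
  one <- function(d, lat, lon) {
    t0 <- as.POSIXct(paste0(format(d), " 00:00:00"), tz = "UTC")
    cross <- sort(c(
      solar_crossings(d, lat, lon, DAY_THRESHOLD_DEG),
      solar_crossings(d, lat, lon, NIGHT_THRESHOLD_DEG)
    ))
    bounds <- as.numeric(c(t0, cross, t0 + 86400))
    mids <- (bounds[-1] + bounds[-length(bounds)]) / 2
    ph <- circadian_phase(as.POSIXct(mids, origin = "1970-01-01", tz = "UTC"), lat, lon)
    widths <- diff(bounds) / 3600
    c(
      day_h = sum(widths[ph == "day"]),
      twilight_h = sum(widths[ph == "twilight"]),
      night_h = sum(widths[ph == "night"])
    )
  }
  res <- t(vapply(seq_along(date), function(i) one(date[i], lat[i], lon[i]), numeric(3)))
  data.frame(
    date = date, lat = lat, lon = lon,
    day_h = res[, "day_h"], twilight_h = res[, "twilight_h"],
    night_h = res[, "night_h"]
  )
}
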