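# Independent oracles used to cross-check the implementation.  These are
# deliberately written along different computational paths than the package
# code (equation-of-time solar geometry instead of sidereal time; direct
# formula evaluation instead of the package's vectorised routines).

# --- solar oracle: altitude via apparent longitude + equation of time ------
oracle_solar_altitude <- function(t, lat, lon) {
  t <- as.POSIXct(t, tz = "UTC")
  jd <- as.numeric(t) / 86400 + 2440587.5
  Tc <- (jd - 2451545) / 36525
  q <- (280.46646 + 36000.76983 * Tc) %% 360           # mean longitude
  g <- (357.52911 + 35999.05029 * Tc) * pi / 180       # mean anomaly
  # equation of centre (three terms)
  cc <- (1.914602 - 0.004817 * Tc) * sin(g) +
    (0.019993 - 0.000101 * Tc) * sin(2 * g) + 0.000289 * sin(3 * g)
  om <- (125.04 - 1934.136 * Tc) * pi / 180
  lam <- (q + cc - 0.00569 - 0.00478 * sin(om)) * pi / 180
  eps <- (23.43929111 - 0.013004167 * Tc + 0.00256 * cos(om)) * pi / 180
  dec <- asin(sin(eps) * sin(lam))

  # equation of time (minutes), Meeus ch. 28 smoothed form
  y <- tan(eps / 2)^2
  e <- 0.016708634 - 0.000042037 * Tc
  qr <- q * pi / 180
  eot <- 4 * (180 / pi) * (
    y * sin(2 * qr) - 2 * e * sin(g) + 4 * e * y * sin(g) * cos(2 * qr) -
      0.5 * y^2 * sin(4 * qr) - 1.25 * e^2 * sin(2 * g)
  )

  frac_min <- (as.numeric(t) %% 86400) / 60
  tst <- frac_min + eot + 4 * lon                        # true solar time, min
  H <- (tst / 4 - 180) * pi / 180                        # hour angle
  phi <- lat * pi / 180
  asin(sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(H)) * 180 / pi
}

# threshold-crossing times on a UTC day by 10-s scan + linear interpolation
oracle_solar_crossings <- function(date, lat, lon, threshold) {
  t0 <- as.POSIXct(paste0(format(as.Date(date)), " 00:00:00"), tz = "UTC")
  s <- seq(0, 86400, by = 10)
  f <- oracle_solar_altitude(t0 + s, lat, lon) - threshold
  i <- which(f[-1] * f[-length(f)] < 0)
  t0 + s[i] + 10 * f[i] / (f[i] - f[i + 1])
}

# --- exactness oracles -----------------------------------------------------
oracle_idw <- function(dists, levels) {
  # plain loop evaluation of sum(w_i * l_i) / sum(w_i), w = 1/d
  num <- 0; den <- 0
  for (i in seq_along(dists)) {
    num <- num + levels[i] / dists[i]
    den <- den + 1 / dists[i]
  }
  num / den
}

oracle_chi2 <- function(obs, props) {
  e <- sum(obs) * props
  total <- 0
  for (i in seq_along(obs)) total <- total + (obs[i] - e[i])^2 / e[i]
  total
}

oracle_speed <- function(ch_from, ch_to, t_dep, t_arr) {
  abs(ch_to - ch_from) / ((as.numeric(t_arr) - as.numeric(t_dep)) / 86400)
}

# --- hand-built tidal annotation with exact interval durations ------------
make_annotation <- function(ebb_h, flood_h, n_cycles = 6,
                            t0 = as.POSIXct("2021-01-01 00:00:00", tz = "UTC"),
                            chainage = 50) {
  starts <- t0
  rows <- list()
  t <- t0
  for (k in seq_len(n_cycles)) {
    rows[[length(rows) + 1]] <- data.frame(
      start = t, end = t + ebb_h * 3600, phase = "ebb", complete = TRUE,
      hw_time = t, stringsAsFactors = FALSE
    )
    t <- t + ebb_h * 3600
    rows[[length(rows) + 1]] <- data.frame(
      start = t, end = t + flood_h * 3600, phase = "flood", complete = TRUE,
      hw_time = t - ebb_h * 3600, stringsAsFactors = FALSE
    )
    t <- t + flood_h * 3600
  }
  structure(
    list(
      location = chainage, station_id = "synthetic",
      intervals = do.call(rbind, rows),
      turning_points = NULL
    ),
    class = "et_tidal_annotation"
  )
}
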