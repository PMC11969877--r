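# Ebb/flood segmentation of water-level series, inverse-distance level
# interpolation to receiver positions, and tidal-cycle statistics.
#
# Phase is defined purely by the changes in water level: an interval from a
# high-water turning point to the next low water is ebb, low to high is
# flood.  Boundaries are half-open [turning point, next turning point), so an
# instant exactly at high water belongs to the starting ebb.

#' Inverse-distance interpolation of water level to a chainage
#'
#' Weighted average of the two chainage-closest stations with weights
#' 1/distance; a station exactly at the target chainage returns its level
#' unchanged, and a single available station is used unweighted.
#'
#' @param series_list list of [water_level_series()] objects.
#' @param target_chainage chainage (km) to interpolate to.
#' @param t POSIXct (UTC), vectorized; rounded to the 10-min grid before
#'   lookup.
#' @return numeric vector of levels (mTAW).
#' @export
interpolate_level <- function(series_list, target_chainage, t) {
  if (!length(series_list)) stop("no water-level stations supplied", call. = FALSE)
  t <- round_to_grid(parse_utc(t))
  d <- abs(vapply(series_list, function(s) s$chainage_km, numeric(1)) - target_chainage)
  ord <- order(d)
  use <- ord[seq_len(min(2L, length(ord)))]
  if (d[use[1]] < 1e-9) use <- use[1]  # coincident station: exact level

  lookup <- function(s) {
    i <- match(as.numeric(t), as.numeric(s$t))
    if (anyNA(i)) {
      stop(
        "timestamp outside water-level coverage of station ", s$station_id,
        call. = FALSE
      )
    }
    s$level[i]
  }
  levels <- vapply(series_list[use], lookup, numeric(length(t)))
  levels <- matrix(levels, nrow = length(t))
  if (length(use) == 1L) {
    return(levels[, 1])
  }
  w <- 1 / d[use]
  as.numeric(levels %*% w) / sum(w)
}

#' Segment a water-level series into alternating ebb/flood intervals
#'
#' Turning points are located on a centred-moving-average smoothed copy of
#' the series (the smoothing suppresses gauge noise; times are reported on
#' the original 10-min grid).  Candidate extrema closer than
#' `min_half_cycle` to an opposite-type neighbour are pruned (wind setup can
#' produce short double extrema), and same-type neighbours keep the more
#' extreme member.  Intervals run max -> min (ebb) and min -> max (flood).
#'
#' @param series a [water_level_series()] (or any list with `t`, `level`,
#'   `chainage_km`).
#' @param min_half_cycle minimum hours between opposite-type turning points.
#' @param smooth_window moving-average window in samples (odd; 7 = 70 min).
#' @return an `et_tidal_annotation`: data.frame `intervals` with columns
#'   `start`, `end`, `phase`, `hw_time` (preceding high water; NA for a
#'   leading flood), plus `location` (chainage) and `turning_points`.
#' @export
segment_phases <- function(series, min_half_cycle = 3, smooth_window = 7L) {
  lv <- series$level
  tt <- series$t
  n <- length(lv)
  if (n < 3) stop("series too short to segment", call. = FALSE)

  k <- as.integer(smooth_window)
  if (k %% 2L == 0L) k <- k + 1L
  if (k > 1L && n > k) {
    sm <- stats::filter(lv, rep(1 / k, k), sides = 2)
    sm <- as.numeric(sm)
    # edges: shrink the window rather than dropping samples
    half <- (k - 1L) %/% 2L
    for (i in which(is.na(sm))) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      sm[i] <- mean(lv[lo:hi])
    }
  } else {
    sm <- lv
  }

  d <- diff(sm)
  s <- sign(d)
  # carry sign through flat stretches so plateau extrema are single events
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  turn <- which(s[-1] != s[-length(s)]) + 1L
  if (!length(turn)) stop("no tidal cycle found in series", call. = FALSE)
  type <- ifelse(s[turn] < 0, "max", "min")  # sign after the point

  cand <- data.frame(idx = turn, type = type, stringsAsFactors = FALSE)

  # prune: enforce alternation (keep more extreme of same-type neighbours),
  # then drop opposite-type pairs closer than min_half_cycle
  repeat {
    changed <- FALSE
    i <- 1L
    while (i < nrow(cand)) {
      if (cand$type[i] == cand$type[i + 1]) {
        a <- sm[cand$idx[i]]; b <- sm[cand$idx[i + 1]]
        keep_first <- if (cand$type[i] == "max") a >= b else a <= b
        cand <- cand[-(i + ifelse(keep_first, 1L, 0L)), , drop = FALSE]
        changed <- TRUE
      } else {
        i <- i + 1L
      }
    }
    sep_h <- diff(as.numeric(tt[cand$idx])) / 3600
    short <- which(sep_h < min_half_cycle)
    if (length(short)) {
      # a too-short half cycle is a spurious wiggle: drop both its endpoints
      j <- short[1]
      drop <- c(j, j + 1L)
      # but never drop a genuine extremum adjacent to a long half-cycle on
      # both sides; drop the *less* prominent endpoint pair member instead
      cand <- cand[-drop, , drop = FALSE]
      changed <- TRUE
    }
    if (!changed) break
  }
  if (nrow(cand) < 2) stop("series does not span a full tidal cycle", call. = FALSE)
  stopifnot(all(cand$type[-1] != cand$type[-nrow(cand)]))

  # A symmetric running mean drags an extremum towards its flatter limb: with
  # adjacent half-cycle durations P (before) and N (after) and limb curvature
  # scaling as 1/duration^2, the balance condition f(t+h) = f(t-h) puts the
  # smoothed extremum at t_true + h (N - P) / (N + P), h = half the window.
  # Subtract that first-order shift and re-round to the sampling grid.
  if (k > 1L && nrow(cand) >= 3) {
    h_samp <- k / 2 # half the (continuous) averaging window, in samples
    idx0 <- cand$idx
    for (i in 2:(nrow(cand) - 1)) {
      # sub-sample extremum of the smoothed series (spline upsampling undoes
      # the grid rounding of the discrete argmax/argmin)
      j <- idx0[i]
      lo <- max(1L, j - 3L); hi <- min(n, j + 3L)
      fine <- stats::spline(lo:hi, sm[lo:hi], n = 61)
      j_sub <- fine$x[if (cand$type[i] == "max") which.max(fine$y) else which.min(fine$y)]
      P <- idx0[i] - idx0[i - 1]
      N <- idx0[i + 1] - idx0[i]
      shift <- h_samp * (N - P) / (N + P)
      cand$idx[i] <- min(max(as.integer(round(j_sub - shift)), 1L), n)
    }
  }

  tp <- data.frame(
    t = tt[cand$idx], type = cand$type, level = lv[cand$idx],
    stringsAsFactors = FALSE
  )
  m <- nrow(tp)
  intervals <- data.frame(
    start = tp$t[-m], end = tp$t[-1],
    phase = ifelse(tp$type[-m] == "max", "ebb", "flood"),
    complete = TRUE,
    stringsAsFactors = FALSE
  )
  # truncated lead/trail segments: phase is known from the level trend, the
  # interval duration is not (excluded from cycle statistics)
  if (tp$t[1] > tt[1]) {
    intervals <- rbind(
      data.frame(
        start = tt[1], end = tp$t[1],
        phase = if (tp$type[1] == "max") "flood" else "ebb",
        complete = FALSE, stringsAsFactors = FALSE
      ),
      intervals
    )
  }
  if (tp$t[m] < tt[n]) {
    intervals <- rbind(
      intervals,
      data.frame(
        start = tp$t[m], end = tt[n],
        phase = if (tp$type[m] == "max") "ebb" else "flood",
        complete = FALSE, stringsAsFactors = FALSE
      )
    )
  }
  # preceding high water for each interval (NA until the first max is seen)
  hw <- as.POSIXct(rep(NA_real_, nrow(intervals)), origin = "1970-01-01", tz = "UTC")
  last_hw <- as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC")
  hw_at <- tp$t[tp$type == "max"]
  for (i in seq_len(nrow(intervals))) {
    cand_hw <- hw_at[hw_at <= intervals$start[i] + 1e-9]
    hw[i] <- if (length(cand_hw)) max(cand_hw) else NA
  }
  intervals$hw_time <- hw

  structure(
    list(
      location = series$chainage_km,
      station_id = series$station_id %||% NA_character_,
      intervals = intervals,
      turning_points = tp
    ),
    class = "et_tidal_annotation"
  )
}

#' Tidal phase and hours since high water at an instant
#'
#' @param annotation an `et_tidal_annotation` from [segment_phases()].
#' @param t POSIXct (UTC), vectorized; rounded to the nearest 10 min first.
#' @return data.frame with columns `phase` ("ebb"/"flood") and `hsh`
#'   (hours since the preceding high water; NA before the first high water).
#' @export
phase_at <- function(annotation, t) {
  t <- round_to_grid(parse_utc(t))
  iv <- annotation$intervals
  starts <- as.numeric(iv$start)
  ends <- as.numeric(iv$end)
  x <- as.numeric(t)
  idx <- findInterval(x, starts)
  bad <- idx == 0 | x >= ends[pmax(idx, 1L)] + 1e-9
  if (any(bad)) {
    # allow the exact final turning point to belong to the last interval
    at_end <- bad & abs(x - ends[length(ends)]) < 1e-9
    idx[at_end] <- nrow(iv)
    bad <- bad & !at_end
  }
  if (any(bad)) {
    stop(
      "timestamp(s) outside tidal annotation span, e.g. ",
      format_utc(t[which(bad)[1]]),
      call. = FALSE
    )
  }
  hsh <- (x - as.numeric(iv$hw_time[idx])) / 3600
  data.frame(phase = iv$phase[idx], hsh = hsh, stringsAsFactors = FALSE)
}

#' Tidal-cycle duration statistics
#'
#' Mean and SD of ebb, flood and full-cycle durations over complete
#' intervals only: the leading interval (unknown true start) and trailing
#' interval (unknown true end) are excluded.
#'
#' @param annotation an `et_tidal_annotation`.
#' @return an `et_cycle_stats` list with `ebb_mean_h`, `ebb_sd_h`,
#'   `flood_mean_h`, `flood_sd_h`, `cycle_mean_h`, `cycle_sd_h`, `n_cycles`.
#' @export
cycle_stats <- function(annotation) {
  iv <- annotation$intervals
  complete <- iv[iv$complete, , drop = FALSE]
  if (nrow(complete) < 4) stop("need at least 2 complete tidal cycles", call. = FALSE)
  dur <- as.numeric(complete$end) - as.numeric(complete$start)
  dur_h <- dur / 3600
  ebb <- dur_h[complete$phase == "ebb"]
  fld <- dur_h[complete$phase == "flood"]
  if (length(ebb) < 2 || length(fld) < 2) {
    stop("need at least 2 complete tidal cycles", call. = FALSE)
  }
  # pair each ebb with the following flood for full-cycle durations
  cyc <- c()
  ph <- complete$phase
  i <- which(ph == "ebb")
  i <- i[i < nrow(complete)]
  cyc <- dur_h[i] + dur_h[i + 1]
  structure(
    list(
      ebb_mean_h = mean(ebb), ebb_sd_h = sd(ebb),
      flood_mean_h = mean(fld), flood_sd_h = sd(fld),
      cycle_mean_h = mean(cyc), cycle_sd_h = sd(cyc),
      n_cycles = length(cyc)
    ),
    class = "et_cycle_stats"
  )
}

#' Tidal annotation at a receiver position
#'
#' Interpolates the two nearest stations' levels to the receiver chainage
#' (inverse-distance weights) and segments the interpolated series —
#' interpolation first, then phase.  When fewer than `min_stations` stations
#' are usable (e.g. the single-gauge transition zone) no annotation is
#' possible and `NULL` is returned; downstream code marks tidal fields
#' `unavailable`.
#'
#' @param series_list list of [water_level_series()].
#' @param receiver_chainage chainage (km).
#' @param min_stations minimum stations required (default 2).
#' @param ... passed to [segment_phases()].
#' @return an `et_tidal_annotation`, or `NULL` when annotation is impossible.
#' @export
annotate_receiver_tide <- function(series_list, receiver_chainage,
                                   min_stations = 2L, ...) {
  if (length(series_list) < min_stations) {
    return(NULL)
  }
  tgrid <- series_list[[1]]$t
  # require a common grid across the two nearest stations
  d <- abs(vapply(series_list, function(s) s$chainage_km, numeric(1)) - receiver_chainage)
  use <- order(d)[1:2]
  t1 <- series_list[[use[1]]]$t
  t2 <- series_list[[use[2]]]$t
  common <- intersect(as.numeric(t1), as.numeric(t2))
  if (length(common) < 3) stop("stations share no common time grid", call. = FALSE)
  tt <- as.POSIXct(sort(common), origin = "1970-01-01", tz = "UTC")
  lv <- interpolate_level(series_list[use], receiver_chainage, tt)
  virtual <- list(
    station_id = paste0("interp@", format(receiver_chainage)),
    chainage_km = receiver_chainage, t = tt, level = lv
  )
  segment_phases(virtual, ...)
}
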