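# Synthetic river / tide / crab / detection simulator.
#
# A 1-D river axis (chainage, km upstream from the estuarine mouth) carries
# three tidal classes: meso/macro-tidal (default 0-125 km), a micro-tidal
# transition (125-136 km) and non-tidal headwaters (136-166 km).  The tide is
# a piecewise-sinusoidal distorted wave: within each 12.4-h period the fall
# (ebb) occupies a chainage-dependent fraction f of the cycle and the rise
# (flood) the remaining 1-f, reproducing the upstream ebb/flood asymmetry of
# lowland estuaries (f rising from 0.508 at the mouth to 0.677 at the
# upstream tidal limit, i.e. ebb 6.3 h -> 8.4 h).
#
# Crabs are downstream-only walkers whose per-step movement gate depends on
# the zone's behavioural mode: "nonselective" (always move), "nocturnal"
# (move unless the sun is up), "stst" (move only during ground-truth ebb),
# or "nocturnal_stst" (both).  Gates are evaluated against the simulator's
# own analytic phases, never against the analysis pipeline's annotations, so
# recovery tests are non-circular.

#' Simulator configuration
#'
#' All defaults describe the emulated study system: a ~166-km river axis
#' with asymmetric semidiurnal tides, zone-dependent movement behaviour
#' (nocturnal in non-tidal water, ebb-selective in tidal water), and an
#' acoustic detection process with configurable ping interval and range.
#'
#' @param seed integer; fully determines the simulator output.
#' @param river_length river axis length, km.
#' @param zone_cuts chainage cut-offs (km): tidal below `zone_cuts[1]`,
#'   transition up to `zone_cuts[2]`, non-tidal beyond.
#' @param anchors 2x2 matrix of (lat, lon) at chainage 0 and at
#'   `river_length`; positions along the axis are linear interpolations
#'   (solar phases need only approximate position).
#' @param tide list: `period_h` (12.4), `ebb_fraction_mouth` (0.508),
#'   `ebb_fraction_upstream` (0.677; both from printed ebb durations 6.3 h
#'   and 8.4 h of a 12.4-h cycle), `amp_mouth_m`, `amp_upstream_m`,
#'   `amp_transition_m`, `mean_level_m`, `noise_sd_m`, `lag_h_per_km`
#'   (upstream phase propagation; 0 = all stations in phase), `t_hw0`
#'   (time of a reference high water at the mouth).
#' @param behaviour list: `modes` and `speed_km_day` per zone (defaults:
#'   non-tidal nocturnal 4.65, transition nocturnal 4.71, tidal stst 1.29
#'   km/day), `jitter_sdlog` (lognormal step jitter, mean 1), `indiv_sdlog`
#'   (per-crab lognormal speed multiplier, default 0 = identical crabs),
#'   `spawn_chainage` (movement ceases permanently here).
#' @param detection list: `range_m` (500; field range 300-1005 m),
#'   `p_det` per-ping detection probability.
#' @param sensor list: `accel_move`, `accel_rest` (0.25 / 0.11 m s^-2),
#'   `accel_sdlog` multiplicative noise, `depth_sd_m`, depth profile knots.
#' @param crabs data.frame of crab metadata, or NULL to generate
#'   `n_crabs` programmatically.
#' @param n_crabs,n_sensor number of crabs / sensor-tagged crabs.
#' @param release_chainage vector (recycled) of release positions, km.
#' @param start UTC timestamp of simulation start.
#' @param days simulated duration.
#' @param step_s trajectory time step, s (default 600 to match the
#'   water-level grid).
#' @param receiver_chainage receiver positions, km.
#' @param station_chainage water-level station positions, km.
#' @param ping_s length-2 ping interval range, s (tag spec 90-150 s).
#' @return an `et_simconfig` list.
#' @export
sim_config <- function(seed = 1L,
                       river_length = 166,
                       zone_cuts = c(125, 136),
                       anchors = rbind(c(51.35, 4.0), c(51.10, 4.75)),
                       tide = list(),
                       behaviour = list(),
                       detection = list(),
                       sensor = list(),
                       crabs = NULL,
                       n_crabs = 10L,
                       n_sensor = 2L,
                       release_chainage = 150,
                       start = "2020-10-05 00:00:00",
                       days = 90,
                       step_s = 600,
                       receiver_chainage = NULL,
                       station_chainage = c(20, 115),
                       ping_s = c(90, 150)) {
  tide <- modifyList(list(
    period_h = 12.4,
    ebb_fraction_mouth = 0.508,
    ebb_fraction_upstream = 0.677,
    amp_mouth_m = 2.5, amp_upstream_m = 1.0, amp_transition_m = 0.4,
    mean_level_m = 2.0, noise_sd_m = 0.02, lag_h_per_km = 0,
    t_hw0 = start
  ), tide)
  behaviour <- modifyList(list(
    modes = c(tidal = "stst", transition = "nocturnal", non_tidal = "nocturnal"),
    speed_km_day = c(tidal = 1.29, transition = 4.71, non_tidal = 4.65),
    jitter_sdlog = 0.3,
    indiv_sdlog = 0, # per-crab lognormal speed multiplier (individual variation)
    spawn_chainage = 60
  ), behaviour)
  detection <- modifyList(list(range_m = 500, p_det = 0.5), detection)
  sensor <- modifyList(list(
    accel_move = 0.25, accel_rest = 0.11, accel_sdlog = 0.35,
    depth_sd_m = 0.2,
    # depth vs chainage: deep estuary mouth shoaling to shallow headwaters
    depth_knots_km = c(0, 125, 136, 166),
    depth_knots_m = c(12.3, 4.8, 3.1, 1.0)
  ), sensor)
  if (is.null(receiver_chainage)) {
    receiver_chainage <- seq(10, 160, length.out = 20)
  }
  ef <- c(tide$ebb_fraction_mouth, tide$ebb_fraction_upstream)
  if (any(ef <= 0 | ef >= 1)) stop("ebb_fraction must lie in (0, 1)", call. = FALSE)
  if (any(behaviour$speed_km_day <= 0)) stop("speeds must be > 0", call. = FALSE)
  if (any(release_chainage < 0 | release_chainage > river_length)) {
    stop("release chainage outside river", call. = FALSE)
  }
  if (!length(station_chainage)) stop("need at least one station", call. = FALSE)

  cfg <- list(
    seed = as.integer(seed), river_length = river_length,
    zone_cuts = zone_cuts, anchors = anchors,
    tide = tide, behaviour = behaviour, detection = detection,
    sensor = sensor, crabs = crabs,
    n_crabs = as.integer(n_crabs), n_sensor = as.integer(n_sensor),
    release_chainage = release_chainage,
    start = parse_utc(start), days = days, step_s = step_s,
    receiver_chainage = sort(receiver_chainage),
    station_chainage = sort(station_chainage),
    ping_s = ping_s
  )
  class(cfg) <- "et_simconfig"
  cfg
}

# linear lat/lon along the axis between the two anchors
position_of_chainage <- function(cfg, ch) {
  w <- pmin(pmax(ch / cfg$river_length, 0), 1)
  list(
    lat = cfg$anchors[1, 1] + w * (cfg$anchors[2, 1] - cfg$anchors[1, 1]),
    lon = cfg$anchors[1, 2] + w * (cfg$anchors[2, 2] - cfg$anchors[1, 2])
  )
}

# ebb fraction of the tidal cycle at a chainage (linear over the tidal zone,
# clamped beyond it)
ebb_fraction_at <- function(cfg, ch) {
  w <- pmin(pmax(ch / cfg$zone_cuts[1], 0), 1)
  cfg$tide$ebb_fraction_mouth +
    w * (cfg$tide$ebb_fraction_upstream - cfg$tide$ebb_fraction_mouth)
}

tide_amplitude_at <- function(cfg, ch) {
  ifelse(ch >= cfg$zone_cuts[2], 0,
    ifelse(ch >= cfg$zone_cuts[1], cfg$tide$amp_transition_m,
      cfg$tide$amp_mouth_m +
        (ch / cfg$zone_cuts[1]) * (cfg$tide$amp_upstream_m - cfg$tide$amp_mouth_m)
    )
  )
}

# cycle phase in [0, 1): 0 = high water at this chainage
tide_cycle_pos <- function(cfg, ch, t_num) {
  period_s <- cfg$tide$period_h * 3600
  lag_s <- cfg$tide$lag_h_per_km * 3600 * ch
  ((t_num - as.numeric(parse_utc(cfg$tide$t_hw0)) - lag_s) %% period_s) / period_s
}

#' Analytic (noise-free) tidal water level of the simulator
#'
#' Piecewise-sinusoidal distorted tide: half-cosine fall over the ebb
#' fraction of the cycle, half-cosine rise over the flood fraction.
#'
#' @param cfg an [sim_config()].
#' @param ch chainage, km.
#' @param t POSIXct or numeric seconds, vectorized.
#' @return level, mTAW.
#' @export
tide_level <- function(cfg, ch, t) {
  t_num <- if (inherits(t, "POSIXct")) as.numeric(t) else t
  s <- tide_cycle_pos(cfg, ch, t_num)
  f <- ebb_fraction_at(cfg, ch)
  shape <- ifelse(s < f,
    cos(pi * s / f),        # ebb: +1 (HW) down to -1 (LW)
    -cos(pi * (s - f) / (1 - f)) # flood: -1 back up to +1
  )
  cfg$tide$mean_level_m + tide_amplitude_at(cfg, ch) * shape
}

#' Ground-truth tidal phase of the simulator
#'
#' @inheritParams tide_level
#' @return logical: TRUE during ebb.
#' @export
tide_is_ebb <- function(cfg, ch, t) {
  t_num <- if (inherits(t, "POSIXct")) as.numeric(t) else t
  tide_cycle_pos(cfg, ch, t_num) < ebb_fraction_at(cfg, ch)
}

#' Simulate water-level series at every configured station
#'
#' @param cfg an [sim_config()].
#' @return list of [water_level_series()], one per station, on a 10-min
#'   grid spanning the simulation, with Gaussian gauge noise of SD
#'   `cfg$tide$noise_sd_m`.
#' @export
simulate_tides <- function(cfg) {
  stopifnot(inherits(cfg, "et_simconfig"))
  set.seed(cfg$seed + 1L)
  t0 <- as.numeric(cfg$start)
  tt <- seq(t0, t0 + cfg$days * 86400, by = 600)
  lapply(seq_along(cfg$station_chainage), function(i) {
    ch <- cfg$station_chainage[i]
    lv <- tide_level(cfg, ch, tt)
    if (cfg$tide$noise_sd_m > 0) lv <- lv + rnorm(length(tt), 0, cfg$tide$noise_sd_m)
    water_level_series(
      station_id = sprintf("S%02d", i), chainage_km = ch,
      t = as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"), level = lv
    )
  })
}

# generate programmatic crab metadata when none supplied
sim_crab_meta <- function(cfg) {
  if (!is.null(cfg$crabs)) {
    return(cfg$crabs)
  }
  set.seed(cfg$seed + 4L)
  n <- cfg$n_crabs
  tag_id <- sprintf("T%03d", seq_len(n))
  rel_ch <- rep_len(cfg$release_chainage, n)
  # staggered releases over the first week, mid-morning (crabs are released
  # the day after capture)
  rel_t <- cfg$start + 86400 * (seq_len(n) %% 7) + 10 * 3600
  data.frame(
    tag_id = tag_id,
    sex = rep_len(c("female", "male"), n),
    cw_mm = round(runif(n, 56, 82), 2),
    mass_g = round(runif(n, 95, 210), 2),
    release_t = rel_t,
    release_chainage_km = rel_ch,
    sensor_tag = seq_len(n) <= cfg$n_sensor,
    ping_min_s = cfg$ping_s[1], ping_max_s = cfg$ping_s[2],
    stringsAsFactors = FALSE
  )
}

#' Simulate crab trajectories
#'
#' Each crab starts at its release chainage/time and steps downstream on the
#' configured grid.  In a step it moves iff its zone's behavioural gate is
#' open (nonselective: always; nocturnal: solar phase is not day; stst:
#' ground-truth tidal phase is ebb; nocturnal_stst: both), covering
#' `speed * step * jitter` km (lognormal jitter with mean 1).  Movement
#' ceases permanently once the spawning chainage is reached.
#'
#' @param cfg an [sim_config()].
#' @return list of trajectory data.frames (`tag_id`, `t`, `chainage_km`,
#'   `moving`, `ebb_truth`, `dark_truth`), plus the crab metadata as
#'   attribute `"crabs"`.
#' @export
simulate_crabs <- function(cfg) {
  stopifnot(inherits(cfg, "et_simconfig"))
  crabs <- sim_crab_meta(cfg)
  set.seed(cfg$seed + 2L)
  t0 <- as.numeric(cfg$start)
  tt <- seq(t0, t0 + cfg$days * 86400, by = cfg$step_s)
  n_steps <- length(tt)

  # precompute "sun is up" on the grid at chainage knots; positions along the
  # axis shift solar times by well under one step, so nearest-knot lookup is
  # adequate for the behavioural gate
  knots <- seq(0, cfg$river_length, length.out = 12)
  pos <- position_of_chainage(cfg, knots)
  dark <- vapply(seq_along(knots), function(k) {
    solar_altitude(
      as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
      pos$lat[k], pos$lon[k]
    ) <= DAY_THRESHOLD_DEG
  }, logical(n_steps))

  period_s <- cfg$tide$period_h * 3600
  hw0 <- as.numeric(parse_utc(cfg$tide$t_hw0))
  cyc <- ((tt - hw0) %% period_s) / period_s # lag 0 form; lag applied below

  cuts <- cfg$zone_cuts
  modes <- cfg$behaviour$modes
  speed_step <- cfg$behaviour$speed_km_day * cfg$step_s / 86400
  spawn <- cfg$behaviour$spawn_chainage
  sdl <- cfg$behaviour$jitter_sdlog
  lag_frac_per_km <- cfg$tide$lag_h_per_km * 3600 / period_s
  ef_m <- cfg$tide$ebb_fraction_mouth
  ef_u <- cfg$tide$ebb_fraction_upstream
  c1 <- cuts[1]; c2 <- cuts[2]
  knot_step <- cfg$river_length / (length(knots) - 1)

  indiv <- if (cfg$behaviour$indiv_sdlog > 0) {
    rlnorm(nrow(crabs), -cfg$behaviour$indiv_sdlog^2 / 2, cfg$behaviour$indiv_sdlog)
  } else {
    rep(1, nrow(crabs))
  }

  out <- vector("list", nrow(crabs))
  for (ci in seq_len(nrow(crabs))) {
    i0 <- which(tt >= as.numeric(crabs$release_t[ci]))[1]
    if (is.na(i0)) {
      out[[ci]] <- NULL
      next
    }
    idx <- i0:n_steps
    m <- length(idx)
    jit <- rlnorm(m, -sdl^2 / 2, sdl)
    ch <- numeric(m)
    moving <- logical(m)
    ebb_tr <- logical(m)
    dark_tr <- logical(m)
    x <- crabs$release_chainage_km[ci]
    stopped <- FALSE
    for (j in seq_len(m)) {
      i <- idx[j]
      f <- if (x >= c1) ef_u else ef_m + (x / c1) * (ef_u - ef_m)
      pos_cyc <- (cyc[i] - lag_frac_per_km * x) %% 1
      is_ebb <- pos_cyc < f
      kk <- round(x / knot_step) + 1
      is_dark <- dark[i, kk]
      ebb_tr[j] <- is_ebb
      dark_tr[j] <- is_dark
      if (!stopped) {
        mode <- if (x < c1) modes[["tidal"]] else if (x < c2) modes[["transition"]] else modes[["non_tidal"]]
        gate <- switch(mode,
          nonselective = TRUE,
          nocturnal = is_dark,
          stst = is_ebb,
          nocturnal_stst = is_dark && is_ebb,
          stop("unknown behaviour mode: ", mode)
        )
        if (gate) {
          sp <- if (x < c1) speed_step[["tidal"]] else if (x < c2) speed_step[["transition"]] else speed_step[["non_tidal"]]
          x2 <- x - sp * indiv[ci] * jit[j]
          if (x2 <= spawn) {
            x2 <- spawn
            stopped <- TRUE
          }
          moving[j] <- x2 < x
          x <- x2
        }
      }
      ch[j] <- x
    }
    out[[ci]] <- data.frame(
      tag_id = crabs$tag_id[ci],
      t = as.POSIXct(tt[idx], origin = "1970-01-01", tz = "UTC"),
      chainage_km = ch, moving = moving,
      ebb_truth = ebb_tr, dark_truth = dark_tr,
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  attr(out, "crabs") <- crabs
  out
}

sim_depth_at <- function(cfg, ch) {
  stats::approx(cfg$sensor$depth_knots_km, cfg$sensor$depth_knots_m,
    xout = pmin(pmax(ch, 0), cfg$river_length), rule = 2
  )$y
}

#' Simulate the acoustic detection process
#'
#' Tags ping at uniform-random intervals within the configured range; a ping
#' is detectable by every receiver within `range_m` along the chainage axis
#' and is logged with probability `p_det`.  Sensor tags attach an
#' acceleration value (moving -> `accel_move`, resting -> `accel_rest`, with
#' multiplicative lognormal noise) and a depth drawn from the depth profile
#' plus the tidal water-level offset in tidal water.
#'
#' @param trajectories output of [simulate_crabs()].
#' @param receivers data.frame with `receiver_id`, `chainage_km`.
#' @param cfg an [sim_config()].
#' @return detections data.frame (`tag_id`, `receiver_id`, `t`,
#'   `accel_ms2`, `depth_m`).
#' @export
simulate_detections <- function(trajectories, receivers, cfg) {
  stopifnot(inherits(cfg, "et_simconfig"))
  if (!nrow(receivers)) stop("empty receiver list", call. = FALSE)
  crabs <- attr(trajectories, "crabs")
  set.seed(cfg$seed + 3L)
  range_km <- cfg$detection$range_m / 1000
  p_det <- cfg$detection$p_det
  rows <- vector("list", length(trajectories))
  for (ci in seq_along(trajectories)) {
    tr <- trajectories[[ci]]
    meta <- crabs[crabs$tag_id == tr$tag_id[1], ]
    t_start <- as.numeric(tr$t[1])
    t_end <- as.numeric(tr$t[nrow(tr)])
    span <- t_end - t_start
    n_max <- ceiling(span / meta$ping_min_s) + 1
    gaps <- runif(n_max, meta$ping_min_s, meta$ping_max_s)
    ping_t <- t_start + cumsum(gaps)
    ping_t <- ping_t[ping_t <= t_end]
    if (!length(ping_t)) next
    ch <- stats::approx(as.numeric(tr$t), tr$chainage_km, xout = ping_t)$y
    step_i <- pmin(
      floor((ping_t - t_start) / cfg$step_s) + 1,
      nrow(tr)
    )
    mov <- tr$moving[step_i]

    sensor <- isTRUE(meta$sensor_tag)
    if (sensor) {
      accel <- ifelse(mov, cfg$sensor$accel_move, cfg$sensor$accel_rest) *
        rlnorm(length(ping_t), -cfg$sensor$accel_sdlog^2 / 2, cfg$sensor$accel_sdlog)
      depth <- sim_depth_at(cfg, ch)
      tidal_part <- ch < cfg$zone_cuts[2]
      depth[tidal_part] <- depth[tidal_part] +
        (tide_level(cfg, ch[tidal_part], ping_t[tidal_part]) - cfg$tide$mean_level_m)
      depth <- pmax(depth + rnorm(length(ping_t), 0, cfg$sensor$depth_sd_m), 0.05)
      accel <- round(accel, 4)
      depth <- round(depth, 2)
    } else {
      accel <- rep(NA_real_, length(ping_t))
      depth <- rep(NA_real_, length(ping_t))
    }

    per_rec <- vector("list", nrow(receivers))
    for (ri in seq_len(nrow(receivers))) {
      in_range <- abs(ch - receivers$chainage_km[ri]) <= range_km
      if (!any(in_range)) next
      heard <- in_range & (runif(length(ping_t)) < p_det)
      if (!any(heard)) next
      per_rec[[ri]] <- data.frame(
        tag_id = tr$tag_id[1],
        receiver_id = receivers$receiver_id[ri],
        t = as.POSIXct(round(ping_t[heard]), origin = "1970-01-01", tz = "UTC"),
        accel_ms2 = accel[heard], depth_m = depth[heard],
        stringsAsFactors = FALSE
      )
    }
    rows[[ci]] <- do.call(rbind, per_rec[!vapply(per_rec, is.null, logical(1))])
  }
  det <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(det)) {
    det <- data.frame(
      tag_id = character(), receiver_id = character(),
      t = as.POSIXct(character(), tz = "UTC"),
      accel_ms2 = numeric(), depth_m = numeric(), stringsAsFactors = FALSE
    )
  }
  det <- det[order(det$tag_id, det$t, det$receiver_id), , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Simulate a complete dataset in memory
#'
#' Runs tides, trajectories and detections for one configuration and
#' assembles an `et_dataset` plus ground truth.
#'
#' @param cfg an [sim_config()].
#' @param config an [analysis_config()] stored with the dataset (zone cuts
#'   are taken from the simulator).
#' @return an `et_dataset` with attribute `"truth"` (list: `trajectories`,
#'   `sim_config`).
#' @export
simulate_dataset <- function(cfg, config = NULL) {
  stopifnot(inherits(cfg, "et_simconfig"))
  if (is.null(config)) {
    config <- analysis_config(zone_cuts = cfg$zone_cuts, seed = cfg$seed)
  }
  wl <- simulate_tides(cfg)
  traj <- simulate_crabs(cfg)
  receivers <- data.frame(
    receiver_id = sprintf("R%03d", seq_along(cfg$receiver_chainage)),
    chainage_km = cfg$receiver_chainage,
    stringsAsFactors = FALSE
  )
  pos <- position_of_chainage(cfg, receivers$chainage_km)
  receivers$lat <- round(pos$lat, 5)
  receivers$lon <- round(pos$lon, 5)
  receivers$zone <- zone_of_chainage(receivers$chainage_km, cfg$zone_cuts)
  receivers <- receivers[, c("receiver_id", "lat", "lon", "chainage_km", "zone")]
  det <- simulate_detections(traj, receivers, cfg)
  crabs <- attr(traj, "crabs")
  ds <- structure(
    list(
      detections = det, receivers = receivers, crabs = crabs,
      water_levels = wl, config = config, n_duplicates_dropped = 0L
    ),
    class = "et_dataset"
  )
  attr(ds, "truth") <- list(trajectories = traj, sim_config = cfg)
  ds
}

#' Built-in simulator profiles
#'
#' `"small"` is a fast fixture (10 crabs over 14 days, releases spread over
#' all three zones, 20 receivers, 2 tidal stations) that runs in seconds;
#' `"paper_like"` emulates the study scale (10 crabs over 90 days released
#' in the non-tidal headwaters, 2 sensor crabs, 4 tidal + 1 transition
#' stations).
#'
#' @param profile `"small"` or `"paper_like"`.
#' @param seed integer seed.
#' @return an [sim_config()].
#' @export
sim_profile <- function(profile = c("small", "paper_like"), seed = 42L) {
  profile <- match.arg(profile)
  if (profile == "small") {
    sim_config(
      seed = seed,
      days = 14,
      n_crabs = 10L, n_sensor = 2L,
      release_chainage = c(110, 90, 70, 45, 128, 134, 150, 155, 160, 145),
      receiver_chainage = seq(10, 160, length.out = 20),
      station_chainage = c(20, 115),
      detection = list(p_det = 0.5)
    )
  } else {
    sim_config(
      seed = seed,
      days = 90,
      n_crabs = 10L, n_sensor = 2L,
      release_chainage = c(150, 148, 152, 155, 145, 150, 120, 100, 80, 60),
      receiver_chainage = seq(10, 160, length.out = 20),
      station_chainage = c(10, 45, 80, 115, 130),
      detection = list(p_det = 0.5)
    )
  }
}

#' Write a fixture dataset plus ground truth to disk
#'
#' Writes the four canonical CSVs via [write_dataset()] together with
#' `truth_trajectories.csv` (per-step position, movement state and the
#' ground-truth ebb/dark gates).  Output is a pure function of
#' (seed, profile): repeated calls are byte-identical.
#'
#' @param directory output directory.
#' @param seed integer seed.
#' @param profile passed to [sim_profile()].
#' @return the directory, invisibly; the dataset as attribute `"dataset"`.
#' @export
make_fixture <- function(directory, seed = 42L, profile = "small") {
  cfg <- sim_profile(profile, seed)
  ds <- simulate_dataset(cfg)
  write_dataset(ds, directory)
  truth <- attr(ds, "truth")
  tr <- do.call(rbind, truth$trajectories)
  write_csv_stable(
    data.frame(
      tag_id = tr$tag_id, datetime_utc = format_utc(tr$t),
      chainage_km = tr$chainage_km, moving = tr$moving,
      ebb_truth = tr$ebb_truth, dark_truth = tr$dark_truth
    ),
    file.path(directory, "truth_trajectories.csv")
  )
  out <- directory
  attr(out, "dataset") <- ds
  invisible(out)
}
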