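# Shared fixtures, built in code.  The small simulated dataset is cached per
# test session; replicate-style generators used by the acceptance suite are
# deliberately compact so hundreds of replicates fit the time budget.

.fixture_cache <- new.env(parent = emptyenv())

cached_small_dataset <- function(seed = 42) {
  key <- paste0("small-", seed)
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("ebbtrack-fixture-", seed))
    suppressMessages(make_fixture(dir, seed = seed, profile = "small"))
    ds <- suppressMessages(read_dataset(dir, analysis_config(seed = seed)))
    .fixture_cache[[key]] <- list(dir = dir, dataset = ds)
  }
  .fixture_cache[[key]]
}

# compact all-tidal river used by the null-calibration / power replicates:
# 10 crabs sweep ~15 receivers in 15 days, yielding ~150 (tag, receiver)
# visit pairs, the event count of the published tidal tests
replicate_config <- function(seed, mode = c("nonselective", "stst"),
                             speed = NULL) {
  mode <- match.arg(mode)
  if (is.null(speed)) speed <- if (mode == "stst") 9 else 5.5
  start <- as.POSIXct("2020-10-20 00:00:00", tz = "UTC")
  # release times spread over a tidal cycle per crab: a steady walker over
  # evenly spaced receivers would otherwise sample the cycle systematically
  # and deflate the between-event phase variance the null model assumes
  set.seed(seed)
  rel_jit <- runif(10, 0, 12.4 * 3600)
  sim_config(
    seed = seed,
    river_length = 100, zone_cuts = c(95, 98),
    days = 15,
    n_crabs = 10L, n_sensor = 0L,
    start = start,
    crabs = data.frame(
      tag_id = sprintf("T%03d", 1:10),
      sex = rep(c("female", "male"), 5),
      cw_mm = 60, mass_g = 130,
      release_t = start + rel_jit,
      release_chainage_km = 88,
      sensor_tag = FALSE, ping_min_s = 240, ping_max_s = 480,
      stringsAsFactors = FALSE
    ),
    release_chainage = 88,
    behaviour = list(
      modes = c(tidal = mode, transition = mode, non_tidal = mode),
      speed_km_day = c(tidal = speed, transition = speed, non_tidal = speed),
      indiv_sdlog = 0.3, # individual speed variation, as in the real system
      spawn_chainage = 1
    ),
    # irregular receiver spacing, as in a real network
    receiver_chainage = c(
      6, 10, 17, 19, 26, 32, 35, 43, 46, 52, 59, 61, 68, 72, 77
    ),
    station_chainage = c(10, 70),
    detection = list(range_m = 500, p_det = 0.7),
    ping_s = c(240, 480),
    tide = list(noise_sd_m = 0)
  )
}

# events + tidal annotation for one replicate; annotations (identical tide
# across replicates: the tide seed only adds gauge noise, disabled here) can
# be passed in and reused
replicate_events <- function(cfg, annotations = NULL) {
  ds <- simulate_dataset(cfg)
  det <- suppressMessages(exclude_release_day(ds$detections, ds$crabs))
  if (is.null(annotations)) annotations <- annotate_dataset_tides(ds)
  ev <- extract_visits(det, ds$receivers)
  ev <- annotate_events(ev, ds$receivers, annotations)
  list(dataset = ds, events = ev, annotations = annotations)
}

# sensor-observation fixture for mixed-model recovery: full simulator run
# over ebb-selective crabs in the tidal zone, observations labelled with the
# simulator's ground-truth tidal phase (recovery tests the model machinery;
# annotation quality is tested separately against the segmentation oracle)
sensor_recovery_obs <- function(seed) {
  start <- as.POSIXct("2020-11-01 00:00:00", tz = "UTC")
  cfg <- sim_config(
    seed = seed,
    river_length = 100, zone_cuts = c(95, 98),
    days = 12,
    n_crabs = 6L, n_sensor = 6L,
    start = start,
    crabs = data.frame(
      tag_id = sprintf("S%03d", 1:6),
      sex = rep(c("female", "male"), 3),
      cw_mm = 60, mass_g = 130,
      release_t = start + 3600,
      release_chainage_km = c(60, 55, 50, 45, 40, 35),
      sensor_tag = TRUE, ping_min_s = 500, ping_max_s = 900,
      stringsAsFactors = FALSE
    ),
    release_chainage = c(60, 55, 50, 45, 40, 35),
    behaviour = list(
      modes = c(tidal = "stst", transition = "stst", non_tidal = "stst"),
      speed_km_day = c(tidal = 2.5, transition = 2.5, non_tidal = 2.5),
      spawn_chainage = 0.5
    ),
    receiver_chainage = seq(5, 65, by = 6),
    station_chainage = c(10, 70),
    detection = list(range_m = 500, p_det = 0.35),
    ping_s = c(500, 900),
    tide = list(noise_sd_m = 0)
  )
  ds <- simulate_dataset(cfg)
  det <- ds$detections
  det <- det[!is.na(det$accel_ms2), , drop = FALSE]
  ri <- match(det$receiver_id, ds$receivers$receiver_id)
  det$sex <- ds$crabs$sex[match(det$tag_id, ds$crabs$tag_id)]
  det$zone <- "tidal"
  det$circadian <- circadian_phase(det$t, ds$receivers$lat[ri], ds$receivers$lon[ri])
  # ground-truth label: the gate state of the trajectory step that produced
  # the measurement (recovery isolates the model machinery from phase-
  # annotation error, which has its own oracle tests)
  truth <- attr(ds, "truth")$trajectories
  det$tidal <- NA_character_
  for (tr in truth) {
    sel <- which(det$tag_id == tr$tag_id[1])
    if (!length(sel)) next
    idx <- pmin(pmax(
      floor((as.numeric(det$t[sel]) - as.numeric(tr$t[1])) / 600) + 1, 1
    ), nrow(tr))
    det$tidal[sel] <- ifelse(tr$ebb_truth[idx], "ebb", "flood")
  }
  det$hsh <- NA_real_
  det
}

# direct speed-record generator for the speed-model recovery replicates:
# lognormal records around the three printed zone means with tag- and
# receiver-level heterogeneity
speed_recovery_records <- function(seed, n_tags = 24,
                                   zone_means = c(
                                     non_tidal = 4.65, transition = 4.71,
                                     tidal = 1.29
                                   ),
                                   sd_tag = 0.25, sd_rec = 0.15, sd_e = 0.5) {
  set.seed(seed)
  segs <- rbind(
    data.frame(zone = "non_tidal", receiver_id = sprintf("N%02d", 1:4)),
    data.frame(zone = "transition", receiver_id = sprintf("T%02d", 1:3)),
    data.frame(zone = "tidal", receiver_id = sprintf("E%02d", 1:6))
  )
  b_rec <- setNames(rnorm(nrow(segs), 0, sd_rec), segs$receiver_id)
  rows <- lapply(seq_len(n_tags), function(i) {
    b_tag <- rnorm(1, 0, sd_tag)
    mu <- log(zone_means[segs$zone]) + b_tag + b_rec[segs$receiver_id] +
      rnorm(nrow(segs), 0, sd_e)
    data.frame(
      tag_id = sprintf("T%03d", i),
      from_receiver = "X", to_receiver = segs$receiver_id,
      distance_km = 5, elapsed_days = 5 / exp(mu),
      speed_km_day = exp(mu), zone = segs$zone, direction = "downstream",
      sex = if (i %% 2 == 0) "male" else "female",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
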