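make_tide_series <- function(ebb_fraction, days = 6, noise_sd = 0,
                             chainage = 50, seed = 1) {
  cfg <- sim_config(
    seed = seed, days = days,
    station_chainage = chainage,
    tide = list(
      ebb_fraction_mouth = ebb_fraction, ebb_fraction_upstream = ebb_fraction,
      noise_sd_m = noise_sd
    )
  )
  simulate_tides(cfg)[[1]]
}

test_that("inverse-distance interpolation matches the worked examples", {
  t <- as.POSIXct("2021-01-01 05:00:00", tz = "UTC")
  mk <- function(ch, lv) {
    water_level_series(paste0("S", ch), ch, t + c(0, 600), c(lv, lv))
  }
  # stations 1 km and 3 km away: (2.0/1 + 4.0/3) / (1 + 1/3) = 2.5
  expect_equal(interpolate_level(list(mk(9, 2), mk(13, 4)), 10, t), 2.5)
  # equidistant stations average
  expect_equal(interpolate_level(list(mk(8, 1), mk(12, 3)), 10, t), 2.0)
  # coincident station wins exactly
  expect_equal(interpolate_level(list(mk(10, 7.3), mk(13, 1)), 10, t), 7.3)
  # single station: unweighted
  expect_equal(interpolate_level(list(mk(9, 2)), 10, t), 2.0)
  # coverage error
  expect_error(
    interpolate_level(list(mk(9, 2)), 10, t + 86400),
    "outside water-level coverage"
  )
  expect_error(interpolate_level(list(), 10, t), "no water-level stations")
})

test_that("interpolated level lies between the two stations' levels", {
  t <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC") + c(0, 600)
  set.seed(5)
  for (i in 1:25) {
    l1 <- runif(1, -1, 5); l2 <- runif(1, -1, 5)
    c1 <- runif(1, 0, 40); c2 <- runif(1, 60, 100)
    tgt <- runif(1, 41, 59)
    s <- list(
      water_level_series("A", c1, t, rep(l1, 2)),
      water_level_series("B", c2, t, rep(l2, 2))
    )
    v <- interpolate_level(s, tgt, t[1])
    expect_gte(v, min(l1, l2) - 1e-12)
    expect_lte(v, max(l1, l2) + 1e-12)
  }
})

test_that("segmentation recovers symmetric and asymmetric tides", {
  # symmetric: every half cycle 6.2 h within one 10-min sample
  ann <- segment_phases(make_tide_series(0.5))
  st <- cycle_stats(ann)
  expect_equal(st$ebb_mean_h, 6.2, tolerance = 10 / 60 / 6.2)
  expect_equal(st$flood_mean_h, 6.2, tolerance = 10 / 60 / 6.2)

  # Boom-like asymmetry 0.573: ebb ~7.10 h, flood ~5.30 h
  st2 <- cycle_stats(segment_phases(make_tide_series(0.573)))
  expect_equal(st2$ebb_mean_h, 0.573 * 12.4, tolerance = 10 / 60 / 7.1)
  expect_equal(st2$flood_mean_h, 0.427 * 12.4, tolerance = 10 / 60 / 5.3)
  # conservation: ebb + flood means recover the period
  expect_equal(st2$ebb_mean_h + st2$flood_mean_h, 12.4, tolerance = 0.05)
  expect_lte(st2$ebb_sd_h, 10 / 60 + 1e-9)

  # monotone ramp: no cycle
  t <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC") + 600 * (0:100)
  ramp <- water_level_series("S1", 10, t, seq(0, 10, length.out = 101))
  expect_error(segment_phases(ramp), "cycle")
})

test_that("segmentation survives realistic gauge noise", {
  # 2 cm Gaussian gauge noise (the simulator default): mean durations stay
  # within about one 10-min sample of the analytic values
  ann <- segment_phases(make_tide_series(0.677, days = 10, noise_sd = 0.02))
  st <- cycle_stats(ann)
  expect_equal(st$ebb_mean_h, 0.677 * 12.4, tolerance = 0.17 / 8.39)
  expect_equal(st$flood_mean_h, 0.323 * 12.4, tolerance = 0.17 / 4.01)
})

test_that("intervals partition the span and alternate phases", {
  ann <- segment_phases(make_tide_series(0.573, noise_sd = 0.03, seed = 9))
  iv <- ann$intervals
  expect_true(all(as.numeric(iv$end[-nrow(iv)]) == as.numeric(iv$start[-1])))
  expect_true(all(iv$phase[-1] != iv$phase[-nrow(iv)]))
  expect_true(all(iv$end > iv$start))
})

test_that("segmented phases match the analytic tide away from boundaries", {
  cfg <- sim_config(
    seed = 3, days = 6, station_chainage = 50,
    tide = list(noise_sd_m = 0)
  )
  s <- simulate_tides(cfg)[[1]]
  ann <- segment_phases(s)
  truth <- tide_is_ebb(cfg, 50, s$t)
  got <- phase_at(ann, s$t)$phase == "ebb"
  # disagreement allowed only within one sample of a phase boundary
  flips <- which(got != truth)
  if (length(flips)) {
    boundary <- which(diff(truth) != 0)
    near <- vapply(flips, function(i) min(abs(i - boundary)) <= 1, logical(1))
    expect_true(all(near))
  }
  expect_lt(mean(got != truth), 0.02)
})

test_that("phase_at honours boundary and rounding conventions", {
  ann <- make_annotation(6.9, 5.5)
  hw <- ann$intervals$start[1]
  # an instant exactly at high water belongs to the starting ebb
  p <- phase_at(ann, hw)
  expect_identical(p$phase, "ebb")
  expect_equal(p$hsh, 0)
  # HW + 7.0 h with a 6.9-h ebb lies in flood, 7.0 h after HW
  p2 <- phase_at(ann, hw + 7 * 3600)
  expect_identical(p2$phase, "flood")
  expect_equal(p2$hsh, 7.0)
  # nearest-10-min rounding: 12:04:59 -> 12:00, 12:05:00 rounds up
  expect_identical(
    round_to_grid(as.POSIXct("2021-01-01 12:04:59", tz = "UTC")),
    as.POSIXct("2021-01-01 12:00:00", tz = "UTC")
  )
  expect_identical(
    round_to_grid(as.POSIXct("2021-01-01 12:05:00", tz = "UTC")),
    as.POSIXct("2021-01-01 12:10:00", tz = "UTC")
  )
  expect_error(phase_at(ann, hw - 3600), "outside tidal annotation")
})

test_that("cycle_stats excludes truncated intervals and needs 2+ cycles", {
  ann <- make_annotation(6.9, 5.5, n_cycles = 5)
  # mark the leading interval truncated: it must drop out of the stats
  ann$intervals$complete[1] <- FALSE
  st <- cycle_stats(ann)
  expect_equal(st$ebb_mean_h, 6.9)
  expect_equal(st$flood_mean_h, 5.5)
  expect_equal(st$cycle_mean_h, 12.4)
  short <- make_annotation(6.9, 5.5, n_cycles = 1)
  expect_error(cycle_stats(short), "2 complete tidal cycles")
})

test_that("receiver annotation is unavailable with a single usable station", {
  t <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC") + 600 * (0:1000)
  s <- water_level_series("S1", 10, t, sin(2 * pi * (0:1000) / 74))
  expect_null(annotate_receiver_tide(list(s), 12, min_stations = 2))
})
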