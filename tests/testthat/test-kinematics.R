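rec3 <- data.frame(
  receiver_id = c("R1", "R2", "R3"), lat = 51.2, lon = 4.4,
  chainage_km = c(150, 140, 120), zone = c("non_tidal", "non_tidal", "tidal"),
  stringsAsFactors = FALSE
)

mk_visit <- function(tag, rec, arr, dep) {
  data.frame(
    tag_id = tag, receiver_id = rec, zone = NA_character_,
    arrival_t = as.POSIXct(arr, tz = "UTC"),
    departure_t = as.POSIXct(dep, tz = "UTC"),
    n_detections = 2L, stringsAsFactors = FALSE
  )
}

test_that("speed is chainage distance over elapsed time", {
  ev <- rbind(
    mk_visit("A", "R1", "2020-11-01 00:00:00", "2020-11-01 06:00:00"),
    mk_visit("A", "R2", "2020-11-03 06:00:00", "2020-11-03 12:00:00")
  )
  sp <- migration_speeds(ev, rec3)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$distance_km, 10)
  expect_equal(sp$elapsed_days, 2)
  expect_equal(sp$speed_km_day, 5)
  expect_identical(sp$direction, "downstream")
  # midpoint chainage 145 -> non-tidal
  expect_identical(sp$zone, "non_tidal")
  # oracle check
  expect_equal(
    sp$speed_km_day,
    oracle_speed(150, 140, ev$departure_t[1], ev$arrival_t[2]),
    tolerance = 1e-12
  )
})

test_that("segment zone uses the midpoint; upstream flagged; bad clocks drop", {
  ev <- rbind(
    mk_visit("A", "R2", "2020-11-01 00:00:00", "2020-11-01 01:00:00"),
    mk_visit("A", "R3", "2020-11-04 00:00:00", "2020-11-04 06:00:00"),
    mk_visit("A", "R1", "2020-11-06 00:00:00", "2020-11-06 01:00:00")
  )
  sp <- migration_speeds(ev, rec3, zone_cuts = c(125, 136))
  # R2 (140) -> R3 (120): midpoint 130 -> transition
  expect_identical(sp$zone[1], "transition")
  # R3 -> R1 goes upstream
  expect_identical(sp$direction[2], "upstream")

  # overlapping ranges can yield non-positive elapsed: dropped with a message
  ev_bad <- rbind(
    mk_visit("A", "R1", "2020-11-01 00:00:00", "2020-11-01 12:00:00"),
    mk_visit("A", "R2", "2020-11-01 06:00:00", "2020-11-01 18:00:00")
  )
  expect_message(sp2 <- migration_speeds(ev_bad, rec3), "non-positive elapsed")
  expect_equal(nrow(sp2), 0)
})

test_that("per-tag distances telescope when nothing is dropped", {
  fx <- cached_small_dataset(42)
  ds <- fx$dataset
  det <- suppressMessages(exclude_release_day(ds$detections, ds$crabs))
  ev <- extract_visits(det, ds$receivers)
  sp <- suppressMessages(migration_speeds(ev, ds$receivers))
  ch <- ds$receivers$chainage_km
  names(ch) <- ds$receivers$receiver_id
  for (tag in unique(sp$tag_id)) {
    s <- sp[sp$tag_id == tag, ]
    evt <- ev[ev$tag_id == tag, ]
    evt <- evt[order(evt$arrival_t), ]
    span <- abs(ch[[evt$receiver_id[1]]] - ch[[evt$receiver_id[nrow(evt)]]])
    signed <- ifelse(s$direction == "downstream", 1, -1)
    if (nrow(s) == nrow(evt) - 1) {
      expect_equal(sum(s$distance_km * signed), span)
    }
  }
})

test_that("fixture speeds recover the programmed movement rates", {
  # dedicated dense-receiver run: nonselective crab at 4.8 km/day
  cfg <- sim_config(
    seed = 14, days = 12, n_crabs = 4L, n_sensor = 0L,
    river_length = 200, zone_cuts = c(190, 195), release_chainage = 180,
    behaviour = list(
      modes = c(
        tidal = "nonselective", transition = "nonselective",
        non_tidal = "nonselective"
      ),
      speed_km_day = c(tidal = 4.8, transition = 4.8, non_tidal = 4.8),
      spawn_chainage = 1, jitter_sdlog = 0.15
    ),
    receiver_chainage = seq(130, 180, by = 10),
    station_chainage = 50,
    detection = list(p_det = 1, range_m = 200),
    ping_s = c(120, 240)
  )
  ds <- simulate_dataset(cfg)
  ev <- extract_visits(ds$detections, ds$receivers)
  sp <- suppressMessages(migration_speeds(ev, ds$receivers, cfg$zone_cuts))
  sp <- sp[sp$direction == "downstream", ]
  expect_gt(nrow(sp), 10)
  # receiver-to-receiver speed slightly exceeds the walking rate because the
  # clock runs only from leaving one detection range to entering the next:
  # expectation ~ speed * spacing / (spacing - 2 * range)
  expect_equal(median(sp$speed_km_day), 4.8 * 10 / (10 - 0.4), tolerance = 0.1)
})

test_that("depth summary groups by zone and needs pressure data", {
  obs <- data.frame(
    tag_id = rep(c("S1", "S2"), each = 3),
    zone = rep(c("non_tidal", "tidal"), each = 3),
    depth_m = c(1, 1, 1, 4, 5, 6), stringsAsFactors = FALSE
  )
  d <- depth_summary(obs)
  nt <- d[d$zone == "non_tidal", ]
  expect_equal(nt$mean_m, 1)
  expect_equal(nt$sd_m, 0)
  expect_equal(nt$n_crabs, 1)
  expect_equal(d[d$zone == "tidal", "min_m"], 4)
  expect_error(depth_summary(obs[0, ]), "no depth")
})

test_that("sensor linkage annotates only sensor tags", {
  fx <- cached_small_dataset(42)
  ds <- fx$dataset
  ann <- annotate_dataset_tides(ds)
  obs <- link_sensor_phases(ds$detections, ds$crabs, ds$receivers, ann)
  sensor_tags <- ds$crabs$tag_id[ds$crabs$sensor_tag]
  expect_true(all(obs$tag_id %in% sensor_tags))
  expect_gt(nrow(obs), 0)
  # non-sensor tag yields nothing
  crabs_off <- ds$crabs
  crabs_off$sensor_tag <- FALSE
  expect_equal(
    nrow(link_sensor_phases(ds$detections, crabs_off, ds$receivers, ann)), 0
  )
  # tidal phase present exactly where the receiver has an annotation
  has_ann <- !vapply(ann[obs$receiver_id], is.null, logical(1))
  expect_true(all(obs$tidal[has_ann] %in% c("ebb", "flood")))
  expect_true(all(obs$tidal[!has_ann] == "unavailable"))
})
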