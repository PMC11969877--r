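rec_tidal <- data.frame(
  receiver_id = c("R1", "R2"), lat = 51.2, lon = 4.4,
  chainage_km = c(40, 60), zone = "tidal", stringsAsFactors = FALSE
)

mk_events <- function(n, rec = "R1", date = "2020-11-15",
                      tidal = "ebb", zone = "tidal") {
  t <- as.POSIXct(paste(date, "12:00:00"), tz = "UTC") + seq_len(n)
  data.frame(
    tag_id = "A", receiver_id = rec, zone = zone,
    arrival_t = t, departure_t = t, n_detections = 1L,
    arrival_circadian = "day", departure_circadian = "day",
    arrival_tidal = tidal, departure_tidal = tidal,
    arrival_hsh = 0.4, departure_hsh = 0.4, stringsAsFactors = FALSE
  )
}

test_that("expected circadian proportions are date-weighted duration shares", {
  # all events on one date at one receiver: props are that day's fractions
  ev <- mk_events(4, date = "2020-11-15")
  p <- expected_circadian_props(ev, "arrival", receivers = rec_tidal)
  d <- phase_durations(as.Date("2020-11-15"), 51.2, 4.4)
  expect_equal(unname(p), c(d$day_h, d$twilight_h, d$night_h) / 24,
    tolerance = 1e-8
  )
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # two dates weighted 3:1 give the 3:1 weighted mean of daily fractions
  ev2 <- rbind(mk_events(3, date = "2020-11-15"), mk_events(1, date = "2021-02-15"))
  p2 <- expected_circadian_props(ev2, "arrival", receivers = rec_tidal)
  da <- phase_durations(as.Date(c("2020-11-15", "2021-02-15")), 51.2, 4.4)
  manual <- (3 * c(da$day_h[1], da$twilight_h[1], da$night_h[1]) +
    c(da$day_h[2], da$twilight_h[2], da$night_h[2])) / 4 / 24
  expect_equal(unname(p2), manual, tolerance = 1e-8)

  # invariant to ordering and duplication of the event set
  p3 <- expected_circadian_props(ev2[sample(4), ], "arrival", receivers = rec_tidal)
  p4 <- expected_circadian_props(rbind(ev2, ev2), "arrival", receivers = rec_tidal)
  expect_equal(p2, p3)
  expect_equal(p2, p4)

  expect_error(
    expected_circadian_props(ev2[0, ], "arrival", receivers = rec_tidal),
    "no events"
  )
})

test_that("expected tidal proportions are receiver-weighted cycle shares", {
  # Antwerp-like 6.9 h ebb / 5.5 h flood: expected ebb share 6.9/12.4
  ann <- list(R1 = make_annotation(6.9, 5.5))
  p <- expected_tidal_props(mk_events(5), "arrival", ann)
  expect_equal(unname(p["ebb"]), 6.9 / 12.4, tolerance = 1e-12)

  # receivers with ebb shares 0.55 and 0.65 weighted 1:3 -> 0.625
  ann2 <- list(
    R1 = make_annotation(0.55 * 12.4, 0.45 * 12.4),
    R2 = make_annotation(0.65 * 12.4, 0.35 * 12.4)
  )
  ev <- rbind(mk_events(1, "R1"), mk_events(3, "R2"))
  p2 <- expected_tidal_props(ev, "arrival", ann2)
  expect_equal(unname(p2["ebb"]), 0.625, tolerance = 1e-12)

  # symmetric tide: 50/50
  p3 <- expected_tidal_props(mk_events(2), "arrival", list(R1 = make_annotation(6.2, 6.2)))
  expect_equal(unname(p3), c(0.5, 0.5))
})

test_that("chi-squared GOF matches hand evaluation and the oracle", {
  r <- gof_test(c(50, 30, 20), c(0.5, 0.3, 0.2))
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)

  r2 <- gof_test(c(60, 25, 15), c(0.5, 0.3, 0.2))
  expect_equal(r2$chi2, 100 / 50 + 25 / 30 + 25 / 20, tolerance = 1e-12)
  expect_equal(r2$df, 2)

  # two tidal phases: df = 1
  expect_equal(gof_test(c(90, 61), c(0.55, 0.45))$df, 1)

  # oracle equivalence on random tables
  set.seed(31)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    p <- runif(k, 0.2, 1); p <- p / sum(p)
    o <- rmultinom(1, sample(20:300, 1), p)[, 1]
    expect_equal(gof_test(o, p)$chi2, oracle_chi2(o, p), tolerance = 1e-10)
  }

  expect_error(gof_test(c(5, 5), c(1, 0)), "strictly positive")
  expect_error(gof_test(c(5, 5), c(0.6, 0.6)), "sum to 1")
})

test_that("run_selectivity emits the full 8-test battery", {
  fx <- cached_small_dataset(42)
  ds <- fx$dataset
  det <- suppressMessages(exclude_release_day(ds$detections, ds$crabs))
  ann <- annotate_dataset_tides(ds)
  ev <- annotate_events(extract_visits(det, ds$receivers), ds$receivers, ann)
  tab <- suppressMessages(run_selectivity(ev, ds$receivers, ann))
  expect_equal(nrow(tab), 8)
  expect_equal(sum(tab$cycle == "circadian"), 6)
  expect_equal(sum(tab$cycle == "tidal"), 2)
  expect_true(all(tab$df[tab$cycle == "tidal" & tab$n > 0] == 1))
  expect_true(all(tab$df[tab$cycle == "circadian" & tab$n > 0] == 2))
  # observed counts sum to n
  for (i in which(tab$n > 0)) {
    obs <- as.integer(strsplit(tab$observed[i], "|", fixed = TRUE)[[1]])
    expect_equal(sum(obs), tab$n[i])
    props <- as.numeric(strsplit(tab$expected[i], "|", fixed = TRUE)[[1]])
    expect_equal(sum(props), 1, tolerance = 1e-9)
  }
  # empty stratum yields an n = 0 row, not an error
  ev_no_tidal <- ev[ev$zone != "tidal", ]
  tab2 <- suppressMessages(run_selectivity(ev_no_tidal, ds$receivers, ann))
  expect_equal(tab2$n[tab2$cycle == "tidal"], c(0L, 0L))
  expect_true(all(is.na(tab2$p[tab2$cycle == "tidal"])))
})

test_that("rose bins respect widths and conserve counts", {
  ev <- mk_events(3)
  ev$arrival_t <- as.POSIXct("2020-11-15 13:20:00", tz = "UTC") + c(0, 60, 120)
  ev$arrival_hsh <- c(0.4, 0.4, 5.9)
  bins <- rose_bins(ev, "diel")
  arr <- bins[bins$event_type == "arrival", ]
  expect_equal(arr$count[arr$bin_start == 13], 3L)
  expect_equal(sum(arr$count), nrow(ev))

  tb <- rose_bins(ev, "tidal")
  tarr <- tb[tb$event_type == "arrival", ]
  expect_equal(tarr$count[tarr$bin_start == 0], 2L)
  expect_equal(tarr$count[tarr$bin_start == 5.5], 1L)
  expect_equal(sum(tarr$count), 3L)
})
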