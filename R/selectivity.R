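# Selectivity analysis: weighted expected phase proportions under a
# continuous-migration null, chi-squared goodness-of-fit tests, and the
# circular binning behind rose diagrams.
#
# Under continuous (non-selective) migration the number of arrivals or
# departures falling in a phase is proportional to that phase's share of the
# diel or tidal cycle.  Because those shares vary over the season (circadian)
# and along the river (tidal), expected proportions are weighted means: each
# event contributes its own date's phase-duration fractions (circadian) or
# its own receiver's cycle-duration fractions (tidal) — identical to
# weighting dates/receivers by their number of occurrences.

CIRCADIAN_PHASES <- c("day", "twilight", "night")
TIDAL_PHASES <- c("ebb", "flood")

#' Expected circadian phase proportions under continuous migration
#'
#' For each event, the daily durations of day/twilight/night (at the event's
#' receiver position, on the event's UTC date) are divided by 24 h; the
#' expected proportions are the mean over events of these fraction vectors.
#'
#' @param events annotated events.
#' @param event_type `"arrival"` or `"departure"`.
#' @param zone optional zone filter.
#' @param receivers receivers data.frame (coordinates).
#' @return named numeric vector over `c("day", "twilight", "night")`,
#'   summing to 1.
#' @export
expected_circadian_props <- function(events, event_type = c("arrival", "departure"),
                                     zone = NULL, receivers) {
  event_type <- match.arg(event_type)
  if (!is.null(zone)) events <- events[events$zone == zone, , drop = FALSE]
  if (!nrow(events)) stop("no events in stratum", call. = FALSE)
  tcol <- paste0(event_type, "_t")
  ri <- match(events$receiver_id, receivers$receiver_id)
  dates <- utc_date(events[[tcol]])
  # durations depend on (date, receiver); compute unique combinations once
  key <- paste(dates, events$receiver_id)
  uk <- !duplicated(key)
  dur <- phase_durations(dates[uk], receivers$lat[ri][uk], receivers$lon[ri][uk])
  frac <- as.matrix(dur[, c("day_h", "twilight_h", "night_h")]) / 24
  rownames(frac) <- key[uk]
  mat <- frac[key, , drop = FALSE]
  props <- colMeans(mat)
  names(props) <- CIRCADIAN_PHASES
  props
}

#' Expected tidal phase proportions under continuous migration
#'
#' For each tidally annotated event, the expected ebb share is its
#' receiver's mean ebb duration divided by the mean cycle duration (from
#' that receiver's [cycle_stats()]); the expected proportions are the mean
#' over events — i.e. the receiver-occurrence-weighted mean.
#'
#' @param events annotated events (tidal fields present).
#' @param event_type `"arrival"` or `"departure"`.
#' @param tidal_annotations named list from [annotate_dataset_tides()].
#' @return named numeric vector over `c("ebb", "flood")`, summing to 1.
#' @export
expected_tidal_props <- function(events, event_type = c("arrival", "departure"),
                                 tidal_annotations) {
  event_type <- match.arg(event_type)
  pcol <- paste0(event_type, "_tidal")
  events <- events[events[[pcol]] %in% TIDAL_PHASES, , drop = FALSE]
  if (!nrow(events)) stop("no tidally annotated events", call. = FALSE)
  rids <- unique(events$receiver_id)
  ebb_share <- vapply(rids, function(rid) {
    st <- cycle_stats(tidal_annotations[[rid]])
    st$ebb_mean_h / (st$ebb_mean_h + st$flood_mean_h)
  }, numeric(1))
  shares <- ebb_share[match(events$receiver_id, rids)]
  p_ebb <- mean(shares)
  c(ebb = p_ebb, flood = 1 - p_ebb)
}

#' Pearson chi-squared goodness-of-fit test
#'
#' `chi2 = sum((O_i - n p_i)^2 / (n p_i))`, `df = k - 1`, upper-tail p.
#'
#' @param observed_counts integer counts per phase.
#' @param expected_props strictly positive proportions summing to 1.
#' @return list with `chi2`, `df`, `p`, `n`.
#' @export
gof_test <- function(observed_counts, expected_props) {
  stopifnot(length(observed_counts) == length(expected_props))
  if (any(expected_props <= 0)) {
    stop("expected proportions must be strictly positive; drop the phase upstream",
      call. = FALSE
    )
  }
  if (abs(sum(expected_props) - 1) > 1e-8) {
    stop("expected proportions must sum to 1", call. = FALSE)
  }
  n <- sum(observed_counts)
  if (n < 1) stop("need at least one observation", call. = FALSE)
  e <- n * expected_props
  chi2 <- sum((observed_counts - e)^2 / e)
  df <- length(observed_counts) - 1L
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE), n = n)
}

count_phases <- function(x, phases) {
  as.integer(table(factor(x, levels = phases)))
}

#' Run the full selectivity test battery
#'
#' Circadian tests: arrivals and departures, separately per zone (3 phases,
#' df = 2 unless a phase with zero expected duration is dropped).  Tidal
#' tests: arrivals and departures over all tidally annotated events pooled
#' (2 phases, df = 1).  Arrival and departure are always tested separately.
#' Empty strata produce an `n = 0` row with the test skipped.
#'
#' @param events annotated events.
#' @param receivers receivers data.frame.
#' @param tidal_annotations named list from [annotate_dataset_tides()].
#' @param alpha significance level used for the `significant` flag.
#' @return data.frame, one row per test: `cycle`, `event_type`, `stratum`,
#'   per-phase observed counts and expected proportions (JSON-ish packed
#'   columns `phases`, `observed`, `expected`), `n`, `chi2`, `df`, `p`,
#'   `significant`.
#' @export
run_selectivity <- function(events, receivers, tidal_annotations,
                            alpha = 0.05) {
  rows <- list()
  add_row <- function(cycle, event_type, stratum, phases, obs, props) {
    if (is.null(obs)) {
      rows[[length(rows) + 1]] <<- data.frame(
        cycle = cycle, event_type = event_type, stratum = stratum,
        phases = paste(phases, collapse = "|"), observed = "", expected = "",
        n = 0L, chi2 = NA_real_, df = NA_integer_, p = NA_real_,
        significant = NA, stringsAsFactors = FALSE
      )
      return(invisible())
    }
    # phases with zero expected duration in this stratum cannot appear under
    # the null; drop them (df shrinks accordingly)
    keep <- props > 0
    if (any(!keep) && any(obs[!keep] > 0)) {
      stop(
        "observed events in a phase with zero expected duration (",
        paste(phases[!keep & obs > 0], collapse = ", "), ")",
        call. = FALSE
      )
    }
    res <- gof_test(obs[keep], props[keep] / sum(props[keep]))
    rows[[length(rows) + 1]] <<- data.frame(
      cycle = cycle, event_type = event_type, stratum = stratum,
      phases = paste(phases[keep], collapse = "|"),
      observed = paste(obs[keep], collapse = "|"),
      expected = paste(format(props[keep] / sum(props[keep]), digits = 10),
        collapse = "|"
      ),
      n = res$n, chi2 = res$chi2, df = res$df, p = res$p,
      significant = res$p < alpha, stringsAsFactors = FALSE
    )
  }

  for (etype in c("arrival", "departure")) {
    ccol <- paste0(etype, "_circadian")
    for (zone in ZONES) {
      sub <- events[events$zone == zone, , drop = FALSE]
      if (!nrow(sub)) {
        et_log("circadian ", etype, " stratum '", zone, "' empty; test skipped")
        add_row("circadian", etype, zone, CIRCADIAN_PHASES, NULL, NULL)
        next
      }
      obs <- count_phases(sub[[ccol]], CIRCADIAN_PHASES)
      props <- expected_circadian_props(sub, etype, zone = NULL, receivers)
      add_row("circadian", etype, zone, CIRCADIAN_PHASES, obs, props)
    }
  }
  for (etype in c("arrival", "departure")) {
    pcol <- paste0(etype, "_tidal")
    sub <- events[events[[pcol]] %in% TIDAL_PHASES, , drop = FALSE]
    if (!nrow(sub)) {
      et_log("tidal ", etype, " stratum empty; test skipped")
      add_row("tidal", etype, "tidal", TIDAL_PHASES, NULL, NULL)
      next
    }
    obs <- count_phases(sub[[pcol]], TIDAL_PHASES)
    props <- expected_tidal_props(sub, etype, tidal_annotations)
    add_row("tidal", etype, "tidal", TIDAL_PHASES, obs, props)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bin events for rose diagrams
#'
#' Diel mode counts arrivals/departures per 1-h clock bin (UTC); tidal mode
#' per 0.5-h hours-since-high-water bin.
#'
#' @param events annotated events.
#' @param mode `"diel"` or `"tidal"`.
#' @return data.frame `event_type`, `bin_start`, `bin_end`, `count`.
#' @export
rose_bins <- function(events, mode = c("diel", "tidal")) {
  mode <- match.arg(mode)
  out <- list()
  for (etype in c("arrival", "departure")) {
    if (mode == "diel") {
      t <- events[[paste0(etype, "_t")]]
      h <- as.numeric(format(t, "%H", tz = "UTC")) +
        as.numeric(format(t, "%M", tz = "UTC")) / 60
      bin <- floor(h)
      lv <- 0:23
      width <- 1
    } else {
      hsh <- events[[paste0(etype, "_hsh")]]
      hsh <- hsh[!is.na(hsh) &
        events[[paste0(etype, "_tidal")]] %in% TIDAL_PHASES]
      bin <- floor(hsh / 0.5) * 0.5
      lv <- seq(0, max(c(bin, 12)), by = 0.5)
      width <- 0.5
    }
    cnt <- table(factor(bin, levels = lv))
    out[[etype]] <- data.frame(
      event_type = etype, bin_start = as.numeric(names(cnt)),
      bin_end = as.numeric(names(cnt)) + width,
      count = as.integer(cnt), stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
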