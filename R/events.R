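# Visit events: reduce detections to per-crab per-receiver arrival/departure
# pairs and annotate them with circadian and tidal phase.
#
# The first detection of a crab at a receiver is its arrival, the last its
# departure; under selective migration these concentrate in the favourable
# phases, under continuous migration they fall in proportion to phase
# duration.  Detections on the UTC day of release are excluded to avoid bias
# from the release time itself.

#' Extract visit events from detections
#'
#' Default (`split_gap = NULL`) is the paper-count-faithful convention: one
#' event per (tag, receiver) pair, arrival = first detection, departure =
#' last detection, even when the crab oscillated between overlapping
#' receivers in between.  With `split_gap = g` hours, detections at a
#' receiver are split into runs separated by gaps > g, one event per run
#' (sensitivity analysis only).
#'
#' @param detections detections data.frame (`tag_id`, `receiver_id`, `t`).
#' @param receivers receivers data.frame (for the `zone` column).
#' @param split_gap hours, or NULL.
#' @return data.frame of events: `tag_id`, `receiver_id`, `zone`,
#'   `arrival_t`, `departure_t`, `n_detections`.
#' @export
extract_visits <- function(detections, receivers, split_gap = NULL) {
  if (!nrow(detections)) {
    return(data.frame(
      tag_id = character(), receiver_id = character(), zone = character(),
      arrival_t = as.POSIXct(character(), tz = "UTC"),
      departure_t = as.POSIXct(character(), tz = "UTC"),
      n_detections = integer(), stringsAsFactors = FALSE
    ))
  }
  det <- detections[order(detections$tag_id, detections$receiver_id, detections$t), ]
  key <- paste(det$tag_id, det$receiver_id, sep = "\r")
  if (is.null(split_gap)) {
    run <- key
  } else {
    gap_s <- split_gap * 3600
    new_run <- c(
      TRUE,
      key[-1] != key[-length(key)] |
        diff(as.numeric(det$t)) > gap_s
    )
    run <- cumsum(new_run)
  }
  first <- !duplicated(run)
  last <- !duplicated(run, fromLast = TRUE)
  ev <- data.frame(
    tag_id = det$tag_id[first],
    receiver_id = det$receiver_id[first],
    arrival_t = det$t[first],
    departure_t = det$t[last],
    n_detections = as.integer(table(factor(run, levels = unique(run)))),
    stringsAsFactors = FALSE
  )
  ev$zone <- receivers$zone[match(ev$receiver_id, receivers$receiver_id)]
  ev <- ev[order(ev$tag_id, ev$arrival_t, ev$receiver_id), c(
    "tag_id", "receiver_id", "zone", "arrival_t", "departure_t", "n_detections"
  )]
  rownames(ev) <- NULL
  ev
}

#' Exclude detections on each crab's release day
#'
#' Removes detections whose timestamp falls within the UTC calendar day of
#' that crab's release.  Apply to detections *before* event extraction so
#' events are recomputed from the surviving detections, not merely trimmed.
#'
#' @param detections detections data.frame.
#' @param crabs crab metadata with `tag_id`, `release_t`.
#' @return filtered detections; crabs left with zero detections are logged.
#' @export
exclude_release_day <- function(detections, crabs) {
  i <- match(detections$tag_id, crabs$tag_id)
  if (anyNA(i)) {
    stop(
      "detections reference unknown tag_id: ",
      paste(unique(detections$tag_id[is.na(i)]), collapse = ", "),
      call. = FALSE
    )
  }
  release_day <- utc_date(crabs$release_t)[i]
  keep <- utc_date(detections$t) != release_day
  dropped_tags <- setdiff(unique(detections$tag_id), unique(detections$tag_id[keep]))
  if (length(dropped_tags)) {
    et_log(
      "crab(s) detected only on their release day (untracked): ",
      paste(dropped_tags, collapse = ", ")
    )
  }
  n_drop <- sum(!keep)
  if (n_drop) et_log("excluded ", n_drop, " release-day detection(s)")
  detections[keep, , drop = FALSE]
}

#' Annotate visit events with circadian and tidal phase
#'
#' Arrival and departure each get a circadian phase (solar altitude at the
#' receiver's coordinates) and — for receivers with a tidal annotation — a
#' tidal phase plus hours since the preceding high water, after rounding to
#' the nearest 10 min.  Receivers without an annotation (transition and
#' non-tidal zones, where two-station interpolation is impossible) get
#' `"unavailable"`.
#'
#' @param events output of [extract_visits()].
#' @param receivers receivers data.frame.
#' @param tidal_annotations named list (by receiver_id) of
#'   `et_tidal_annotation` or NULL, e.g. from [annotate_dataset_tides()].
#' @return events with added columns `arrival_circadian`,
#'   `departure_circadian`, `arrival_tidal`, `departure_tidal`,
#'   `arrival_hsh`, `departure_hsh`.
#' @export
annotate_events <- function(events, receivers, tidal_annotations = list()) {
  ri <- match(events$receiver_id, receivers$receiver_id)
  lat <- receivers$lat[ri]
  lon <- receivers$lon[ri]
  events$arrival_circadian <- circadian_phase(events$arrival_t, lat, lon)
  events$departure_circadian <- circadian_phase(events$departure_t, lat, lon)

  events$arrival_tidal <- "unavailable"
  events$departure_tidal <- "unavailable"
  events$arrival_hsh <- NA_real_
  events$departure_hsh <- NA_real_
  for (rid in unique(events$receiver_id)) {
    ann <- tidal_annotations[[rid]]
    if (is.null(ann)) next
    sel <- which(events$receiver_id == rid)
    pa <- phase_at(ann, events$arrival_t[sel])
    pd <- phase_at(ann, events$departure_t[sel])
    events$arrival_tidal[sel] <- pa$phase
    events$departure_tidal[sel] <- pd$phase
    events$arrival_hsh[sel] <- pa$hsh
    events$departure_hsh[sel] <- pd$hsh
  }
  events
}

#' Tidal annotations for every tidal-zone receiver of a dataset
#'
#' Interpolates water levels to each tidal-zone receiver chainage from the
#' two nearest tidal-zone stations (inverse-distance weights) and segments
#' the interpolated series.  Receivers outside the tidal zone, or zones with
#' fewer than `min_stations` stations, yield no annotation.
#'
#' @param dataset an `et_dataset`.
#' @return named list (receiver_id -> `et_tidal_annotation` or NULL).
#' @export
annotate_dataset_tides <- function(dataset) {
  cfg <- dataset$config
  rec <- dataset$receivers
  tidal_stations <- Filter(
    function(s) zone_of_chainage(s$chainage_km, cfg$zone_cuts) == "tidal",
    dataset$water_levels
  )
  out <- setNames(vector("list", nrow(rec)), rec$receiver_id)
  for (i in seq_len(nrow(rec))) {
    if (rec$zone[i] != "tidal") next
    out[[rec$receiver_id[i]]] <- annotate_receiver_tide(
      tidal_stations, rec$chainage_km[i],
      min_stations = cfg$min_stations_tidal,
      min_half_cycle = cfg$min_half_cycle,
      smooth_window = cfg$smooth_window
    )
  }
  out
}
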