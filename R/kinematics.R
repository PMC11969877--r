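# Kinematics: migration speed between consecutive receivers, per-zone depth
# summaries, and sensor-to-phase linkage for the acceleration models.

#' Migration speeds between consecutive receivers
#'
#' For each crab, consecutive distinct-receiver visit pairs (events ordered
#' by arrival time) yield `distance = |chainage difference|` and
#' `elapsed = arrival at next - departure at previous`; speed is km/day.
#' The segment's zone is the zone of the midpoint chainage.  Records with
#' non-positive elapsed time (clock anomalies from overlapping detection
#' ranges) are dropped and logged; zero-distance pairs (revisits under
#' split-gap mode) are skipped.  Upstream displacements (chainage increase)
#' are flagged `direction = "upstream"` and excluded from the speed model
#' downstream.
#'
#' @param events events data.frame from [extract_visits()].
#' @param receivers receivers data.frame.
#' @param zone_cuts chainage cut-offs, as in [analysis_config()].
#' @return data.frame of speed records: `tag_id`, `from_receiver`,
#'   `to_receiver`, `distance_km`, `elapsed_days`, `speed_km_day`, `zone`,
#'   `direction`.
#' @export
migration_speeds <- function(events, receivers, zone_cuts = c(125, 136)) {
  ev <- events[order(events$tag_id, events$arrival_t), ]
  ch <- receivers$chainage_km[match(ev$receiver_id, receivers$receiver_id)]
  out <- list()
  n_dropped <- 0L
  for (tag in unique(ev$tag_id)) {
    sel <- which(ev$tag_id == tag)
    if (length(sel) < 2) next
    for (k in seq_len(length(sel) - 1)) {
      i <- sel[k]; j <- sel[k + 1]
      if (ev$receiver_id[i] == ev$receiver_id[j]) next # revisit: zero distance
      dist <- abs(ch[j] - ch[i])
      elapsed <- (as.numeric(ev$arrival_t[j]) - as.numeric(ev$departure_t[i])) / 86400
      if (elapsed <= 0) {
        n_dropped <- n_dropped + 1L
        next
      }
      out[[length(out) + 1]] <- data.frame(
        tag_id = tag,
        from_receiver = ev$receiver_id[i], to_receiver = ev$receiver_id[j],
        distance_km = dist, elapsed_days = elapsed,
        speed_km_day = dist / elapsed,
        zone = zone_of_chainage((ch[i] + ch[j]) / 2, zone_cuts),
        direction = if (ch[j] > ch[i]) "upstream" else "downstream",
        stringsAsFactors = FALSE
      )
    }
  }
  if (n_dropped) {
    et_log("dropped ", n_dropped, " speed record(s) with non-positive elapsed time")
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    tag_id = character(), from_receiver = character(), to_receiver = character(),
    distance_km = numeric(), elapsed_days = numeric(), speed_km_day = numeric(),
    zone = character(), direction = character(), stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

#' Depth summaries per zone
#'
#' @param sensor_obs output of [link_sensor_phases()] (needs `depth_m`,
#'   `zone`, `tag_id`).
#' @return data.frame per zone: `n_crabs`, `n_obs`, `mean_m`, `sd_m`,
#'   `min_m`, `max_m`.
#' @export
depth_summary <- function(sensor_obs) {
  obs <- sensor_obs[!is.na(sensor_obs$depth_m), , drop = FALSE]
  if (!nrow(obs)) stop("no depth observations", call. = FALSE)
  out <- lapply(split(obs, obs$zone), function(g) {
    data.frame(
      zone = g$zone[1],
      n_crabs = length(unique(g$tag_id)),
      n_obs = nrow(g),
      mean_m = mean(g$depth_m), sd_m = sd(g$depth_m),
      min_m = min(g$depth_m), max_m = max(g$depth_m),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  res <- res[order(match(res$zone, ZONES)), ]
  rownames(res) <- NULL
  res
}

#' Link sensor detections to circadian and tidal phase
#'
#' Every detection carrying an acceleration or depth payload is annotated
#' with circadian phase (receiver coordinates) and, where the receiver has a
#' tidal annotation, tidal phase and hours since high water (after 10-min
#' rounding).  Non-sensor tags yield zero observations.
#'
#' @param detections detections data.frame.
#' @param crabs crab metadata (`sensor_tag`, `sex`).
#' @param receivers receivers data.frame.
#' @param tidal_annotations named list from [annotate_dataset_tides()].
#' @return data.frame of sensor observations: `tag_id`, `receiver_id`, `t`,
#'   `accel_ms2`, `depth_m`, `sex`, `zone`, `circadian`, `tidal`, `hsh`.
#' @export
link_sensor_phases <- function(detections, crabs, receivers, tidal_annotations) {
  sensor_tags <- crabs$tag_id[crabs$sensor_tag]
  obs <- detections[detections$tag_id %in% sensor_tags &
    (!is.na(detections$accel_ms2) | !is.na(detections$depth_m)), , drop = FALSE]
  if (!nrow(obs)) {
    return(data.frame(
      tag_id = character(), receiver_id = character(),
      t = as.POSIXct(character(), tz = "UTC"),
      accel_ms2 = numeric(), depth_m = numeric(), sex = character(),
      zone = character(), circadian = character(), tidal = character(),
      hsh = numeric(), stringsAsFactors = FALSE
    ))
  }
  ri <- match(obs$receiver_id, receivers$receiver_id)
  obs$sex <- crabs$sex[match(obs$tag_id, crabs$tag_id)]
  obs$zone <- receivers$zone[ri]
  obs$circadian <- circadian_phase(obs$t, receivers$lat[ri], receivers$lon[ri])
  obs$tidal <- "unavailable"
  obs$hsh <- NA_real_
  for (rid in unique(obs$receiver_id)) {
    ann <- tidal_annotations[[rid]]
    if (is.null(ann)) next
    sel <- which(obs$receiver_id == rid)
    pa <- phase_at(ann, obs$t[sel])
    obs$tidal[sel] <- pa$phase
    obs$hsh[sel] <- pa$hsh
  }
  rownames(obs) <- NULL
  obs
}
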