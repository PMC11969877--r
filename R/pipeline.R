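# End-to-end orchestration: events -> tidal/solar annotation -> selectivity
# -> kinematics -> inference, with CSV outputs, a JSON manifest and a
# plain-text summary.  Given (dataset, config), output files are
# byte-identical across runs.

#' Run the full analysis pipeline
#'
#' @param dataset an `et_dataset` (from [read_dataset()] or
#'   [simulate_dataset()]).
#' @param out_dir output directory for CSVs, manifest and summary; NULL to
#'   skip writing.
#' @return list of result tables and fitted models, invisibly when writing.
#' @export
run_pipeline <- function(dataset, out_dir = NULL) {
  stopifnot(inherits(dataset, "et_dataset"))
  cfg <- dataset$config
  stage <- "events"
  res <- tryCatch(
    {
      det <- exclude_release_day(dataset$detections, dataset$crabs)
      events <- extract_visits(det, dataset$receivers, split_gap = cfg$split_gap)

      stage <- "tides/solar annotation"
      tides <- annotate_dataset_tides(dataset)
      events <- annotate_events(events, dataset$receivers, tides)

      stage <- "selectivity"
      selectivity <- run_selectivity(events, dataset$receivers, tides,
        alpha = cfg$alpha
      )
      roses <- rbind(
        cbind(mode = "diel", rose_bins(events, "diel")),
        cbind(mode = "tidal", rose_bins(events, "tidal"))
      )

      stage <- "kinematics"
      speeds <- migration_speeds(events, dataset$receivers, cfg$zone_cuts)
      if (!cfg$keep_upstream) {
        speeds <- speeds[speeds$direction == "downstream", , drop = FALSE]
      }
      sensor_obs <- link_sensor_phases(
        det, dataset$crabs, dataset$receivers, tides
      )
      depth <- if (any(!is.na(sensor_obs$depth_m))) depth_summary(sensor_obs) else NULL

      stage <- "inference"
      accel_fits <- if (nrow(sensor_obs)) {
        fit_acceleration_models(sensor_obs)
      } else {
        warning("no sensor tags in dataset; acceleration models skipped",
          call. = FALSE
        )
        list()
      }
      speed_fit <- if (nrow(speeds[speeds$direction == "downstream", ]) >= 4 &&
        length(unique(speeds$zone)) >= 2) {
        sp2 <- speeds
        sp2$sex <- dataset$crabs$sex[match(sp2$tag_id, dataset$crabs$tag_id)]
        fit_speed_model(sp2)
      } else {
        warning("too few speed records for the speed model; skipped",
          call. = FALSE
        )
        NULL
      }
      list(
        events = events, selectivity = selectivity, rose_bins = roses,
        speeds = speeds, sensor_obs = sensor_obs, depth_summary = depth,
        accel_fits = accel_fits, speed_fit = speed_fit,
        tidal_annotations = tides
      )
    },
    error = function(e) {
      stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )

  if (!is.null(out_dir)) {
    tables <- list(
      events = events_to_table(res$events),
      selectivity = res$selectivity,
      rose_bins = res$rose_bins,
      speeds = res$speeds,
      depth_summary = res$depth_summary %||% data.frame()
    )
    notes <- list()
    for (zone in names(res$accel_fits)) {
      tt <- fit_to_tables(res$accel_fits[[zone]])
      tables[[paste0("model_accel_", zone)]] <- tt$coefficients
      tables[[paste0("model_accel_", zone, "_means")]] <- tt$means
      tables[[paste0("model_accel_", zone, "_contrasts")]] <- tt$contrasts
      notes[[paste0("accel_", zone, "_selection")]] <- tt$selection
      if (!is.null(res$accel_fits[[zone]]$fallback_note)) {
        notes[[paste0("accel_", zone, "_fallback")]] <-
          res$accel_fits[[zone]]$fallback_note
      }
    }
    if (!is.null(res$speed_fit)) {
      tt <- fit_to_tables(res$speed_fit)
      tables$model_speed <- tt$coefficients
      tables$model_speed_means <- tt$means
      tables$model_speed_contrasts <- tt$contrasts
      notes$speed_selection <- tt$selection
    }
    write_results(tables, out_dir, cfg, extra = list(notes = notes))
    writeLines(pipeline_summary(res), file.path(out_dir, "summary.txt"))
  }
  invisible(res)
}

events_to_table <- function(ev) {
  data.frame(
    tag_id = ev$tag_id, receiver_id = ev$receiver_id, zone = ev$zone,
    arrival_t = format_utc(ev$arrival_t), departure_t = format_utc(ev$departure_t),
    n_detections = ev$n_detections,
    arrival_circadian = ev$arrival_circadian,
    departure_circadian = ev$departure_circadian,
    arrival_tidal = ev$arrival_tidal, departure_tidal = ev$departure_tidal,
    arrival_hsh = ev$arrival_hsh, departure_hsh = ev$departure_hsh,
    stringsAsFactors = FALSE
  )
}

# plain-text digest mirroring the usual results structure
pipeline_summary <- function(res) {
  out <- c("== selectivity tests ==")
  s <- res$selectivity
  for (i in seq_len(nrow(s))) {
    out <- c(out, sprintf(
      "%-9s %-9s %-10s n=%3d  chi2=%8.3f df=%s p=%s%s",
      s$cycle[i], s$event_type[i], s$stratum[i], s$n[i],
      ifelse(is.na(s$chi2[i]), NA, s$chi2[i]), s$df[i],
      format.pval(s$p[i], digits = 3),
      ifelse(isTRUE(s$significant[i]), " *", "")
    ))
  }
  out <- c(out, "", "== migration speed (km/day, downstream records) ==")
  sp <- res$speeds[res$speeds$direction == "downstream", ]
  for (z in intersect(ZONES, unique(sp$zone))) {
    v <- sp$speed_km_day[sp$zone == z]
    out <- c(out, sprintf(
      "%-10s n=%4d  mean=%6.2f sd=%6.2f range=%.2f-%.2f",
      z, length(v), mean(v), sd(v), min(v), max(v)
    ))
  }
  if (!is.null(res$depth_summary)) {
    out <- c(out, "", "== depth (m) ==")
    d <- res$depth_summary
    for (i in seq_len(nrow(d))) {
      out <- c(out, sprintf(
        "%-10s n_crabs=%d n_obs=%5d mean=%6.2f sd=%5.2f range=%.2f-%.2f",
        d$zone[i], d$n_crabs[i], d$n_obs[i], d$mean_m[i], d$sd_m[i],
        d$min_m[i], d$max_m[i]
      ))
    }
  }
  for (zone in names(res$accel_fits)) {
    f <- res$accel_fits[[zone]]
    out <- c(out, "", paste0("== acceleration model, ", zone, " zone =="))
    out <- c(out, paste0("  retained: ", terms_to_rhs(f$retained_terms)))
    if (!is.null(f$means$tidal)) {
      m <- f$means$tidal
      for (i in seq_len(nrow(m))) {
        out <- c(out, sprintf(
          "  %s: %.2f m/s^2 [%.2f-%.2f]",
          m$level[i], m$mean[i], m$lower[i], m$upper[i]
        ))
      }
    }
    if (!is.null(f$means$circadian)) {
      m <- f$means$circadian
      for (i in seq_len(nrow(m))) {
        out <- c(out, sprintf(
          "  %s: %.2f m/s^2 [%.2f-%.2f]",
          m$level[i], m$mean[i], m$lower[i], m$upper[i]
        ))
      }
    }
  }
  if (!is.null(res$speed_fit)) {
    f <- res$speed_fit
    out <- c(out, "", "== speed model ==")
    out <- c(out, paste0("  retained: ", terms_to_rhs(f$retained_terms)))
    if (!is.null(f$means$zone)) {
      m <- f$means$zone
      for (i in seq_len(nrow(m))) {
        out <- c(out, sprintf(
          "  %s: %.2f km/day [%.2f-%.2f]",
          m$level[i], m$mean[i], m$lower[i], m$upper[i]
        ))
      }
    }
    if (!is.null(f$contrasts$zone)) {
      ct <- f$contrasts$zone
      for (i in seq_len(nrow(ct))) {
        out <- c(out, sprintf(
          "  %s: ratio=%.2f p(Tukey)=%s",
          ct$contrast[i], ct$ratio[i], format.pval(ct$p[i], digits = 3)
        ))
      }
    }
  }
  out
}
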