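# Domain containers and validated CSV readers/writers.
#
# A telemetry dataset is four plain-CSV tables:
#   detections.csv  tag_id, receiver_id, datetime_utc, accel_ms2, depth_m
#   receivers.csv   receiver_id, lat, lon, chainage_km, zone
#   crabs.csv       tag_id, sex, cw_mm, mass_g, release_datetime_utc,
#                   release_chainage_km, sensor_tag, ping_min_s, ping_max_s
#   waterlevels.csv station_id, chainage_km, datetime_utc, level_mtaw
#
# Chainage is km upstream from the estuarine mouth, so downstream movement is
# decreasing chainage.  Zones partition the river axis: tidal < cut1,
# transition [cut1, cut2), non_tidal >= cut2.

ZONES <- c("tidal", "transition", "non_tidal")
SEXES <- c("female", "male")

.required_cols <- list(
  detections  = c("tag_id", "receiver_id", "datetime_utc", "accel_ms2", "depth_m"),
  receivers   = c("receiver_id", "lat", "lon", "chainage_km", "zone"),
  crabs       = c("tag_id", "sex", "cw_mm", "mass_g", "release_datetime_utc",
                  "release_chainage_km", "sensor_tag", "ping_min_s", "ping_max_s"),
  waterlevels = c("station_id", "chainage_km", "datetime_utc", "level_mtaw")
)

read_table_checked <- function(path, what) {
  if (!file.exists(path)) {
    stop("missing input file: ", path, call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- .required_cols[[what]]
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(
      "schema mismatch in ", basename(path), ": missing column(s) ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  df[need]
}

#' Zone of a chainage position
#'
#' @param chainage_km numeric vector, km upstream from the estuarine mouth.
#' @param cuts numeric length-2: `c(tidal_max, transition_max)`; tidal is
#'   `[0, cuts[1])`, transition `[cuts[1], cuts[2])`, non-tidal beyond.
#' @return character vector in `c("tidal", "transition", "non_tidal")`.
#' @export
zone_of_chainage <- function(chainage_km, cuts = c(125, 136)) {
  stopifnot(length(cuts) == 2, cuts[1] < cuts[2])
  ifelse(chainage_km < cuts[1], "tidal",
    ifelse(chainage_km < cuts[2], "transition", "non_tidal")
  )
}

#' Analysis configuration
#'
#' Bundles every tunable of the analysis pipeline so a run is reproducible
#' from (dataset, config) alone.
#'
#' @param zone_cuts chainage cut-offs (km) separating tidal / transition /
#'   non-tidal river sections.
#' @param smooth_window water-level smoothing window (samples) used before
#'   turning-point detection.
#' @param min_half_cycle minimum separation (h) between a high and a low
#'   water; guards against double extrema from wind setup.
#' @param split_gap optional gap (h) above which detections at one receiver
#'   are split into separate visits; `NULL` reproduces the first/last-
#'   detection convention used for the published event counts.
#' @param alpha significance level for the goodness-of-fit tests.
#' @param seed integer seed recorded in the manifest.
#' @param min_stations_tidal minimum number of usable water-level stations
#'   for a receiver to get a tidal annotation (2: inverse-distance
#'   interpolation needs two stations; zones with a single station are
#'   marked `unavailable`).
#' @param keep_upstream keep upstream speed records (flagged) in speeds.csv;
#'   they are excluded from the speed model either way.
#' @return an `et_config` list.
#' @export
analysis_config <- function(zone_cuts = c(125, 136),
                            smooth_window = 7L,
                            min_half_cycle = 3,
                            split_gap = NULL,
                            alpha = 0.05,
                            seed = 1L,
                            min_stations_tidal = 2L,
                            keep_upstream = TRUE) {
  cfg <- list(
    zone_cuts = as.numeric(zone_cuts),
    smooth_window = as.integer(smooth_window),
    min_half_cycle = as.numeric(min_half_cycle),
    split_gap = if (is.null(split_gap)) NULL else as.numeric(split_gap),
    alpha = as.numeric(alpha),
    seed = as.integer(seed),
    min_stations_tidal = as.integer(min_stations_tidal),
    keep_upstream = isTRUE(keep_upstream)
  )
  class(cfg) <- "et_config"
  cfg
}

#' Read and validate a telemetry dataset directory
#'
#' Loads the four CSV tables, normalizes timestamps to UTC, sorts detections
#' by (tag, time), drops exact duplicate (tag, receiver, time) triples
#' (keeping the first; count reported), and enforces referential integrity:
#' every detection must reference a known tag and receiver.
#'
#' @param directory path containing `detections.csv`, `receivers.csv`,
#'   `crabs.csv`, `waterlevels.csv`.
#' @param config an [analysis_config()].
#' @return an `et_dataset` list with elements `detections`, `receivers`,
#'   `crabs`, `water_levels` (a list of per-station series), `config`.
#' @export
read_dataset <- function(directory, config = analysis_config()) {
  stopifnot(inherits(config, "et_config"))
  det <- read_table_checked(file.path(directory, "detections.csv"), "detections")
  rec <- read_table_checked(file.path(directory, "receivers.csv"), "receivers")
  crb <- read_table_checked(file.path(directory, "crabs.csv"), "crabs")
  wl  <- read_table_checked(file.path(directory, "waterlevels.csv"), "waterlevels")

  det$tag_id <- as.character(det$tag_id)
  det$receiver_id <- as.character(det$receiver_id)
  det$t <- parse_utc(det$datetime_utc)
  det$datetime_utc <- NULL
  det$accel_ms2 <- as.numeric(det$accel_ms2)
  det$depth_m <- as.numeric(det$depth_m)

  rec$receiver_id <- as.character(rec$receiver_id)
  if (anyDuplicated(rec$receiver_id)) {
    stop("duplicate receiver_id in receivers.csv", call. = FALSE)
  }
  if (anyDuplicated(rec$chainage_km)) {
    stop("receiver chainage values must be unique", call. = FALSE)
  }
  expected_zone <- zone_of_chainage(rec$chainage_km, config$zone_cuts)
  bad_zone <- which(rec$zone != expected_zone)
  if (length(bad_zone)) {
    stop(
      "receiver zone inconsistent with chainage cut-offs: ",
      paste(rec$receiver_id[bad_zone], collapse = ", "),
      call. = FALSE
    )
  }

  crb$tag_id <- as.character(crb$tag_id)
  if (anyDuplicated(crb$tag_id)) stop("duplicate tag_id in crabs.csv", call. = FALSE)
  if (!all(crb$sex %in% SEXES)) {
    stop("crabs.csv column sex must be 'female' or 'male'", call. = FALSE)
  }
  crb$release_t <- parse_utc(crb$release_datetime_utc)
  crb$release_datetime_utc <- NULL
  crb$sensor_tag <- as.logical(crb$sensor_tag)

  # referential integrity
  unknown_tag <- setdiff(unique(det$tag_id), crb$tag_id)
  if (length(unknown_tag)) {
    stop(
      "detections reference unknown tag_id: ",
      paste(unknown_tag, collapse = ", "),
      call. = FALSE
    )
  }
  unknown_rec <- setdiff(unique(det$receiver_id), rec$receiver_id)
  if (length(unknown_rec)) {
    stop(
      "detections reference unknown receiver_id: ",
      paste(unknown_rec, collapse = ", "),
      call. = FALSE
    )
  }

  # drop duplicate triples, keep first occurrence in file order
  key <- paste(det$tag_id, det$receiver_id, as.numeric(det$t), sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    et_log("dropped ", sum(dup), " duplicate detection(s)")
    det <- det[!dup, , drop = FALSE]
  }
  det <- det[order(det$tag_id, det$t, det$receiver_id), , drop = FALSE]
  rownames(det) <- NULL

  wl$station_id <- as.character(wl$station_id)
  wl$t <- parse_utc(wl$datetime_utc)
  wl$datetime_utc <- NULL
  series <- lapply(split(wl, wl$station_id), function(s) {
    s <- s[order(s$t), , drop = FALSE]
    water_level_series(
      station_id = s$station_id[1], chainage_km = s$chainage_km[1],
      t = s$t, level = s$level_mtaw
    )
  })
  series <- series[order(vapply(series, function(s) s$chainage_km, numeric(1)))]

  structure(
    list(
      detections = det, receivers = rec[order(rec$chainage_km), ],
      crabs = crb, water_levels = unname(series), config = config,
      n_duplicates_dropped = sum(dup)
    ),
    class = "et_dataset"
  )
}

#' Construct a water-level series
#'
#' Validates the 10-min sampling contract: strictly increasing timestamps;
#' spacing other than 600 s is flagged in `gaps` (row indices before a gap),
#' never silently interpolated.
#'
#' @param station_id station identifier.
#' @param chainage_km station position, km upstream from the mouth.
#' @param t POSIXct timestamps (UTC).
#' @param level water level, mTAW.
#' @export
water_level_series <- function(station_id, chainage_km, t, level) {
  t <- parse_utc(t)
  stopifnot(length(t) == length(level))
  dt <- diff(as.numeric(t))
  if (any(dt <= 0)) stop("water-level timestamps must strictly increase", call. = FALSE)
  gaps <- which(abs(dt - 600) > 1e-6)
  if (length(gaps)) {
    et_log(
      "station ", station_id, ": ", length(gaps),
      " irregular sampling interval(s) flagged"
    )
  }
  structure(
    list(
      station_id = as.character(station_id),
      chainage_km = as.numeric(chainage_km),
      t = t, level = as.numeric(level), gaps = gaps
    ),
    class = "et_wls"
  )
}

#' @export
print.et_dataset <- function(x, ...) {
  cat(
    "<et_dataset> ", nrow(x$detections), " detections, ",
    nrow(x$crabs), " crabs, ", nrow(x$receivers), " receivers, ",
    length(x$water_levels), " water-level stations\n",
    sep = ""
  )
  invisible(x)
}

#' Write a dataset to a directory as the four canonical CSVs
#'
#' Inverse of [read_dataset()]: `read_dataset(write_dataset(ds, d))` is the
#' identity on content.
#'
#' @param dataset an `et_dataset`.
#' @param directory output path (created if needed).
#' @export
write_dataset <- function(dataset, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  det <- dataset$detections
  write_csv_stable(
    data.frame(
      tag_id = det$tag_id, receiver_id = det$receiver_id,
      datetime_utc = format_utc(det$t),
      accel_ms2 = det$accel_ms2, depth_m = det$depth_m
    ),
    file.path(directory, "detections.csv")
  )
  write_csv_stable(dataset$receivers, file.path(directory, "receivers.csv"))
  crb <- dataset$crabs
  write_csv_stable(
    data.frame(
      tag_id = crb$tag_id, sex = crb$sex, cw_mm = crb$cw_mm, mass_g = crb$mass_g,
      release_datetime_utc = format_utc(crb$release_t),
      release_chainage_km = crb$release_chainage_km,
      sensor_tag = crb$sensor_tag,
      ping_min_s = crb$ping_min_s, ping_max_s = crb$ping_max_s
    ),
    file.path(directory, "crabs.csv")
  )
  wl <- do.call(rbind, lapply(dataset$water_levels, function(s) {
    data.frame(
      station_id = s$station_id, chainage_km = s$chainage_km,
      datetime_utc = format_utc(s$t), level_mtaw = s$level
    )
  }))
  write_csv_stable(wl, file.path(directory, "waterlevels.csv"))
  invisible(directory)
}

#' Write per-stage result tables plus a reproducibility manifest
#'
#' One CSV per table and a `manifest.json` recording input hashes, the
#' configuration, seed and package version.  Re-running on identical inputs
#' reproduces byte-identical CSVs (no wall-clock values are written).
#'
#' @param results named list of data.frames.
#' @param directory output directory.
#' @param config the [analysis_config()] used.
#' @param extra optional named list merged into the manifest (e.g. filter
#'   counts, model-selection paths).
#' @return invisibly, the manifest list.
#' @export
write_results <- function(results, directory, config = analysis_config(),
                          extra = list()) {
  stopifnot(is.list(results), all(nzchar(names(results))))
  ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    stop("cannot create output directory: ", directory, call. = FALSE)
  }
  files <- list()
  for (nm in names(results)) {
    tab <- results[[nm]]
    stopifnot(is.data.frame(tab))
    path <- file.path(directory, paste0(nm, ".csv"))
    write_csv_stable(tab, path)
    files[[nm]] <- list(
      file = basename(path),
      rows = nrow(tab),
      sha256 = digest::digest(file = path, algo = "sha256")
    )
    if (nrow(tab) == 0) et_log("table '", nm, "' written with zero rows")
  }
  manifest <- c(
    list(
      package = "ebbtrack",
      version = as.character(packageVersion("ebbtrack")),
      config = unclass(config),
      config_hash = digest::digest(unclass(config), algo = "sha256"),
      tables = files
    ),
    extra
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA
  )
  invisible(manifest)
}
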