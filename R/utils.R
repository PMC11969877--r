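# Internal helpers: UTC time handling, grid rounding, logging.

#' Parse timestamps to POSIXct in UTC
#'
#' Accepts ISO-8601 strings with or without offset designator and normalizes
#' everything to UTC.  All timestamps inside the package are POSIXct with
#' `tzone = "UTC"`.
#'
#' @param x character vector of timestamps, or POSIXct.
#' @return POSIXct vector in UTC.
#' @keywords internal
parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- as.character(x)
  # Try strict ISO-8601 with offset first, then space-separated, then date.
  out <- as.POSIXct(x,
    tryFormats = c(
      "%Y-%m-%dT%H:%M:%OS%z", "%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
      "%Y-%m-%d %H:%M:%OS%z", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"
    ),
    tz = "UTC"
  )
  if (anyNA(out) && !anyNA(x)) {
    bad <- x[is.na(out)][1]
    stop("unparseable timestamp: ", bad, call. = FALSE)
  }
  out
}

#' Format timestamps as ISO-8601 UTC strings
#' @param t POSIXct vector.
#' @keywords internal
format_utc <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Round a timestamp to the nearest 10-minute grid point
#'
#' Detection times are rounded to the nearest 10 min to match the temporal
#' resolution of the water-level series; exact midpoints (mm:05:00) round up.
#'
#' @param t POSIXct vector (UTC).
#' @param step_s grid spacing in seconds (default 600).
#' @return POSIXct vector on the grid.
#' @export
#' @examples
#' round_to_grid(as.POSIXct("2020-10-05 12:04:59", tz = "UTC"))
round_to_grid <- function(t, step_s = 600) {
  secs <- as.numeric(t)
  as.POSIXct(floor((secs + step_s / 2) / step_s) * step_s,
    origin = "1970-01-01", tz = "UTC"
  )
}

#' UTC calendar date of a timestamp
#' @keywords internal
utc_date <- function(t) as.Date(t, tz = "UTC")

# Messaging: all pipeline filters report what they dropped so runs are
# auditable; routed through message() so callers can suppressMessages().
et_log <- function(...) message("[ebbtrack] ", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic CSV writer: fixed column order, no row names, "" for NA,
# full precision for doubles (byte-stable given identical input).
write_csv_stable <- function(df, path) {
  stopifnot(is.data.frame(df))
  for (nm in names(df)) {
    if (inherits(df[[nm]], "POSIXct")) df[[nm]] <- format_utc(df[[nm]])
    if (is.numeric(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(v) {
        if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
      }, character(1))
    }
  }
  write.csv(df, path, row.names = FALSE, na = "", quote = TRUE, eol = "\n")
  invisible(path)
}
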