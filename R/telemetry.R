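# Telemetry: fix tables, calendars, collar summaries.

#' Season calendar
#'
#' Weeks are half-open 7-day blocks anchored at `week1_start` (week 1 of the
#' shorebird nesting season, conventionally 14 April): a timestamp `t` falls
#' in week `1 + floor((t - week1_start) / 7 days)`.
#'
#' @param week1_start First day of week 1.
#' @param n_weeks Number of weeks in the season.
#' @param nesting_end_week Last week of the nesting season (mid April to
#'   mid July is weeks 1-12).
#' @return A list of class `season_calendar`.
#' @export
season_calendar <- function(week1_start = as.Date("2013-04-14"),
                            n_weeks = 28L, nesting_end_week = 12L) {
  stopifnot(n_weeks >= 1, nesting_end_week >= 1)
  structure(list(week1_start = as.Date(week1_start),
                 n_weeks = as.integer(n_weeks),
                 nesting_end_week = as.integer(nesting_end_week)),
            class = "season_calendar")
}

#' Construct a set of collar tracks
#'
#' @param fixes Data frame with columns `collar_id`, `timestamp` (POSIXct),
#'   `x_m`, `y_m`; sorted by collar then time on construction.
#' @param herd_size Herd size (>= number of distinct collars).
#' @param marsh_id Marsh identifier.
#' @param grazing_start,grazing_end Grazing window dates (defaults: the fix
#'   date range).
#' @param seed Optional RNG seed recorded for provenance.
#' @return An object of class `track_set`.
#' @export
track_set <- function(fixes, herd_size, marsh_id = "M",
                      grazing_start = NULL, grazing_end = NULL, seed = NULL) {
  need <- c("collar_id", "timestamp", "x_m", "y_m")
  if (!all(need %in% names(fixes)))
    stop("fixes must have columns: ", paste(need, collapse = ", "))
  if (!inherits(fixes$timestamp, "POSIXct"))
    stop("fixes$timestamp must be POSIXct")
  if (any(!is.finite(fixes$x_m)) || any(!is.finite(fixes$y_m)))
    stop("fix coordinates must be finite")
  fixes <- fixes[order(fixes$collar_id, fixes$timestamp), , drop = FALSE]
  rownames(fixes) <- NULL
  n_collars <- length(unique(fixes$collar_id))
  if (herd_size < n_collars)
    stop("herd_size (", herd_size, ") < number of collars (", n_collars, ")")
  dates <- as.Date(fixes$timestamp, tz = "UTC")
  structure(list(fixes = fixes, herd_size = herd_size, marsh_id = marsh_id,
                 grazing_start = as.Date(grazing_start %||% min(dates)),
                 grazing_end = as.Date(grazing_end %||% max(dates)),
                 seed = seed),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set %s: %d fixes, %d collars, herd %d, %s to %s\n",
              x$marsh_id, nrow(x$fixes), length(unique(x$fixes$collar_id)),
              x$herd_size, x$grazing_start, x$grazing_end))
  invisible(x)
}

#' Per-collar logging spans
#'
#' @param tracks A `track_set`.
#' @return Data frame `collar_id, first_fix, last_fix, n_fixes`.
#' @export
collar_spans <- function(tracks) {
  f <- tracks$fixes
  sp <- do.call(rbind, lapply(split(f, f$collar_id), function(d) {
    data.frame(collar_id = d$collar_id[1], first_fix = min(d$timestamp),
               last_fix = max(d$timestamp), n_fixes = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  sp
}

.parse_iso8601 <- function(s) {
  t <- as.POSIXct(s, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                 "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"),
                  optional = TRUE)
  t
}

#' Read GPS fixes from CSV or GPX
#'
#' The CSV dialect is `collar_id,timestamp,x_m,y_m` with ISO-8601 timestamps.
#' GPX 1.1 waypoints carry the collar id in `<name>`, the timestamp in
#' `<time>`, and planar metres in the `lat`/`lon` attributes (local
#' projected pseudo-CRS; this package's analyses are planar throughout).
#' Duplicate (collar, timestamp) pairs are hardware artefacts: the first is
#' kept and the number dropped is reported in the `n_duplicates` attribute.
#'
#' @param path Input file.
#' @param format `"csv"`, `"gpx"`, or `"auto"` (by file extension).
#' @param herd_size Herd size for the resulting [track_set()].
#' @param marsh_id Marsh identifier.
#' @param grazing_start,grazing_end Optional grazing window dates.
#' @return A [track_set()]; attributes `n_duplicates` and `spans` carry the
#'   dedup count and the per-collar span report.
#' @export
read_fixes <- function(path, format = c("auto", "csv", "gpx"),
                       herd_size, marsh_id = "M",
                       grazing_start = NULL, grazing_end = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gpx$", path, ignore.case = TRUE)) "gpx" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(raw) == 0) stop("empty fix file: ", path)
    need <- c("collar_id", "timestamp", "x_m", "y_m")
    if (!all(need %in% names(raw)))
      stop("fix CSV must have columns: ", paste(need, collapse = ", "))
    ts <- .parse_iso8601(raw$timestamp)
    if (anyNA(ts))
      stop("unparseable timestamp(s) at row(s): ",
           paste(utils::head(which(is.na(ts)), 10), collapse = ", "))
    fixes <- data.frame(collar_id = as.character(raw$collar_id),
                        timestamp = ts, x_m = as.numeric(raw$x_m),
                        y_m = as.numeric(raw$y_m), stringsAsFactors = FALSE)
  } else {
    doc <- xml2::read_xml(path)
    ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
    wpts <- xml2::xml_find_all(doc, ".//g:wpt", ns)
    if (length(wpts) == 0) wpts <- xml2::xml_find_all(doc, ".//wpt")
    if (length(wpts) == 0) stop("empty fix file: ", path)
    ts <- .parse_iso8601(vapply(wpts, function(w)
      xml2::xml_text(xml2::xml_find_first(w, ".//*[local-name()='time']")),
      character(1)))
    if (anyNA(ts))
      stop("unparseable timestamp(s) at waypoint(s): ",
           paste(utils::head(which(is.na(ts)), 10), collapse = ", "))
    fixes <- data.frame(
      collar_id = vapply(wpts, function(w)
        xml2::xml_text(xml2::xml_find_first(w, ".//*[local-name()='name']")),
        character(1)),
      timestamp = ts,
      x_m = as.numeric(xml2::xml_attr(wpts, "lon")),
      y_m = as.numeric(xml2::xml_attr(wpts, "lat")),
      stringsAsFactors = FALSE)
  }
  fixes <- fixes[order(fixes$collar_id, fixes$timestamp), , drop = FALSE]
  dup <- duplicated(fixes[, c("collar_id", "timestamp")])
  n_dup <- sum(dup)
  if (n_dup > 0) {
    message(n_dup, " duplicate (collar, timestamp) fix(es) dropped")
    fixes <- fixes[!dup, , drop = FALSE]
  }
  ts_out <- track_set(fixes, herd_size = herd_size, marsh_id = marsh_id,
                      grazing_start = grazing_start, grazing_end = grazing_end)
  attr(ts_out, "n_duplicates") <- n_dup
  attr(ts_out, "spans") <- collar_spans(ts_out)
  ts_out
}

#' Write fixes to the CSV dialect
#'
#' @param tracks A [track_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fixes_csv <- function(tracks, path) {
  f <- tracks$fixes
  out <- data.frame(collar_id = f$collar_id,
                    timestamp = format(f$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                       tz = "UTC"),
                    x_m = f$x_m, y_m = f$y_m)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write fixes to the GPX dialect
#'
#' Planar metres are stored in the `lat`/`lon` attributes (see
#' [read_fixes()]).
#'
#' @inheritParams write_fixes_csv
#' @return `path`, invisibly.
#' @export
write_fixes_gpx <- function(tracks, path) {
  f <- tracks$fixes
  wpts <- sprintf(
    '  <wpt lat="%.6f" lon="%.6f"><time>%s</time><name>%s</name></wpt>',
    f$y_m, f$x_m,
    format(f$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"), f$collar_id)
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               '<gpx version="1.1" creator="saltgraze" xmlns="http://www.topografix.com/GPX/1/1">',
               wpts, '</gpx>'), path)
  invisible(path)
}

#' Cattle days recorded by active collars
#'
#' The number of distinct calendar days with at least one fix, summed over
#' collars.
#'
#' @param tracks A [track_set()].
#' @return Integer count of collar-days.
#' @export
cattle_days <- function(tracks) {
  f <- tracks$fixes
  if (nrow(f) == 0) stop("empty track set")
  days <- unique(data.frame(collar_id = f$collar_id,
                            day = as.Date(f$timestamp, tz = "UTC")))
  nrow(days)
}

#' Label fixes with season week indices
#'
#' Weeks are half-open 7-day blocks from the calendar's `week1_start` (see
#' [season_calendar()]). Re-labelling already-labelled tracks is a no-op.
#'
#' @param tracks A [track_set()].
#' @param cal A [season_calendar()].
#' @return The track set with a `week` column on its fixes.
#' @export
assign_weeks <- function(tracks, cal) {
  stopifnot(inherits(cal, "season_calendar"))
  f <- tracks$fixes
  wk1 <- as.POSIXct(paste(cal$week1_start, "00:00:00"), tz = "UTC")
  wk <- 1 + floor(as.numeric(difftime(f$timestamp, wk1, units = "days")) / 7)
  bad <- wk < 1 | wk > cal$n_weeks
  if (any(bad))
    stop("fix(es) outside the season calendar: ",
         paste(format(utils::head(f$timestamp[bad], 10),
                      "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"), collapse = ", "))
  tracks$fixes$week <- as.integer(wk)
  tracks$calendar <- cal
  tracks
}
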