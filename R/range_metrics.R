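# Weekly range and habitat-use summaries: CA100, never-visited fraction,
# zone activity shares, 95th-percentile distance to the sea wall.

#' CA100: percentage of included cells holding all the week's activity
#'
#' The smallest set of grid cells containing 100% of a week's cattle
#' activity is exactly the set of visited cells, so CA100 is the visited
#' fraction of the available (included) marsh, in percent. Large CA100 means
#' the herd's activity is spread out.
#'
#' @param activity An `activity_grid` (weekly, not pooled).
#' @param week Week index.
#' @return Percentage in (0, 100], or `NA` for a week with no fixes.
#' @export
ca100 <- function(activity, week) {
  stopifnot(inherits(activity, "activity_grid"))
  n_inc <- sum(activity$cells$included)
  if (!week %in% activity$week_totals$week) return(NA_real_)
  visited <- sum(activity$counts$week == week & activity$counts$n >= 1,
                 na.rm = TRUE)
  100 * visited / n_inc
}

#' Percentage of the available marsh never visited
#'
#' Included cells with no fix in any week of the activity surface.
#'
#' @param activity An `activity_grid` covering the full season.
#' @return Percentage in [0, 100].
#' @export
never_visited_fraction <- function(activity) {
  stopifnot(inherits(activity, "activity_grid"))
  inc <- activity$cells$cell_id[activity$cells$included]
  visited <- unique(activity$counts$cell_id[activity$counts$n >= 1])
  100 * sum(!inc %in% visited) / length(inc)
}

#' Zone shares of weekly cattle activity
#'
#' For each habitat zone, the percentage of the week's included-cell fixes
#' that fell in cells labelled with that zone, together with the zone's
#' share of the total marsh area (the "Area" reference bars).
#'
#' @param activity An `activity_grid` with zones assigned.
#' @param week Week index (or `NULL` with a pooled surface).
#' @return Data frame `zone, share_pct, area_pct`.
#' @export
zone_activity_share <- function(activity, week = NULL) {
  stopifnot(inherits(activity, "activity_grid"))
  cells <- activity$cells
  if (all(is.na(cells$zone))) stop("grid has no zone labels")
  counts <- activity$counts
  if (activity$pooled) {
    if (!is.null(week)) stop("pooled surface has no weeks")
  } else {
    if (is.null(week)) stop("week required for a weekly surface")
    counts <- counts[counts$week == week, , drop = FALSE]
  }
  counts$zone <- cells$zone[match(counts$cell_id, cells$cell_id)]
  zl <- zone_levels[zone_levels %in% unique(stats::na.omit(cells$zone))]
  nz <- vapply(zl, function(z) sum(counts$n[counts$zone %in% z]), 0)
  inc_area <- cells$marsh_area_m2[cells$included]
  inc_zone <- cells$zone[cells$included]
  az <- vapply(zl, function(z) sum(inc_area[inc_zone %in% z]), 0)
  data.frame(zone = zl,
             share_pct = 100 * nz / sum(nz),
             area_pct = 100 * az / sum(az),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' 95th percentile of fix distances to the sea wall
#'
#' Pooled over collars within a week; the 95th percentile (type-7 linear
#' interpolation between order statistics) excludes one-off excursions and
#' tracks the furthest distance the herd ranges.
#'
#' @param tracks A [track_set()] with week labels.
#' @param seawall Sea-wall polyline matrix.
#' @param week Week index; `NULL` uses all fixes.
#' @param min_n Weeks with fewer fixes are flagged via the `low_n` attribute.
#' @return Distance in metres (`NA` for an empty week).
#' @export
p95_distance <- function(tracks, seawall, week = NULL, min_n = 20) {
  f <- tracks$fixes
  if (!is.null(week)) {
    if (is.null(f$week)) stop("fixes carry no week labels")
    f <- f[f$week == week, , drop = FALSE]
  }
  if (nrow(f) == 0) return(NA_real_)
  d <- dist_to_polyline(f$x_m, f$y_m, seawall)
  out <- as.numeric(stats::quantile(d, 0.95, type = 7))
  attr(out, "low_n") <- nrow(f) < min_n
  out
}

#' Weekly range-metric series
#'
#' One row per week with fixes: CA100, the 95th-percentile distance to the
#' sea wall, and fix counts.
#'
#' @param tracks A [track_set()] with week labels.
#' @param activity A weekly `activity_grid` built from `tracks`.
#' @param seawall Sea-wall polyline matrix.
#' @return Data frame `marsh, week, n_fixes, ca100_pct, p95_dist_m`.
#' @export
weekly_metrics <- function(tracks, activity, seawall) {
  stopifnot(inherits(activity, "activity_grid"), !activity$pooled)
  weeks <- sort(activity$week_totals$week)
  out <- data.frame(
    marsh = tracks$marsh_id,
    week = weeks,
    n_fixes = activity$week_totals$n_included[
      match(weeks, activity$week_totals$week)],
    ca100_pct = vapply(weeks, function(w) ca100(activity, w), 0),
    p95_dist_m = vapply(weeks, function(w)
      as.numeric(p95_distance(tracks, seawall, w)), 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
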