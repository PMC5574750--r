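# 50 x 50 m analysis grid: construction, inclusion rule, zone assignment,
# and the cattle-activity statistic.

#' Build the analysis grid over a marsh
#'
#' Lays a square grid over the bounding box of the marsh boundary. Cells are
#' half-open `[x, x+s) x [y, y+s)` anchored at the bounding-box minimum (or
#' a supplied origin). Each cell's marsh area is the area of the cell
#' intersected with the boundary minus any creek overlap; cells are included
#' in analyses only when they contain more than `inclusion_threshold_m2` of
#' saltmarsh (6.25 m2, the square of the nominal 2.5 m GPS accuracy).
#'
#' @param marsh A [marsh_geometry()].
#' @param cell_size_m Cell side length in metres.
#' @param origin Optional `c(x, y)` grid origin.
#' @param inclusion_threshold_m2 Strict lower bound on marsh area per
#'   included cell.
#' @return A `marsh_grid`: data frame `cell_id, ix, iy, x0, y0, cx, cy,
#'   marsh_area_m2, included, zone, dist_seawall_m` with grid metadata in
#'   attributes.
#' @export
build_grid <- function(marsh, cell_size_m = 50, origin = NULL,
                       inclusion_threshold_m2 = 6.25) {
  stopifnot(inherits(marsh, "marsh_geometry"), cell_size_m > 0)
  if (poly_area(marsh$boundary) <= 0)
    stop("degenerate marsh boundary (zero area)")
  bb <- .poly_bbox(marsh$boundary)
  if (is.null(origin)) origin <- c(bb[1], bb[3])
  nx <- ceiling((bb[2] - origin[1]) / cell_size_m - 1e-9)
  ny <- ceiling((bb[4] - origin[2]) / cell_size_m - 1e-9)
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  x0 <- origin[1] + ix * cell_size_m
  y0 <- origin[2] + iy * cell_size_m
  n <- length(x0)
  area <- numeric(n)
  for (i in seq_len(n)) {
    a <- poly_rect_area(marsh$boundary, x0[i], x0[i] + cell_size_m,
                        y0[i], y0[i] + cell_size_m)
    if (a > 0 && length(marsh$creeks))
      a <- a - sum(vapply(marsh$creeks, poly_rect_area, 0,
                          xmin = x0[i], xmax = x0[i] + cell_size_m,
                          ymin = y0[i], ymax = y0[i] + cell_size_m))
    area[i] <- max(a, 0)
  }
  cells <- data.frame(
    cell_id = sprintf("c%04d_%04d", ix, iy),
    ix = ix, iy = iy, x0 = x0, y0 = y0,
    cx = x0 + cell_size_m / 2, cy = y0 + cell_size_m / 2,
    marsh_area_m2 = area,
    included = area > inclusion_threshold_m2,
    zone = NA_character_,
    stringsAsFactors = FALSE)
  cells$dist_seawall_m <- dist_to_polyline(cells$cx, cells$cy, marsh$seawall)
  structure(cells, class = c("marsh_grid", "data.frame"),
            cell_size_m = cell_size_m, origin = origin,
            inclusion_threshold_m2 = inclusion_threshold_m2,
            marsh_id = marsh$marsh_id)
}

#' Locate points on a grid
#'
#' Half-open cell convention: a point on a shared edge belongs to the cell
#' with the larger index.
#'
#' @param grid A `marsh_grid`.
#' @param x,y Point coordinates in metres.
#' @return Data frame `cell_id, included` per point (`NA` cell for points
#'   off the grid).
#' @export
locate_cells <- function(grid, x, y) {
  cs <- attr(grid, "cell_size_m")
  org <- attr(grid, "origin")
  ix <- floor((x - org[1]) / cs)
  iy <- floor((y - org[2]) / cs)
  key <- paste(ix, iy)
  m <- match(key, paste(grid$ix, grid$iy))
  data.frame(cell_id = grid$cell_id[m],
             included = ifelse(is.na(m), FALSE, grid$included[m]),
             stringsAsFactors = FALSE)
}

#' Assign habitat zones to grid cells by majority area
#'
#' Each included cell is labelled with the habitat zone occupying the
#' largest area of the cell; exact ties are broken toward the zone nearer
#' the sea wall in the fixed zone order ([zone_levels]).
#'
#' @param grid A `marsh_grid` from [build_grid()].
#' @param marsh The [marsh_geometry()] holding the zone polygons.
#' @return The grid with its `zone` column filled for included cells.
#' @export
assign_zones <- function(grid, marsh) {
  stopifnot(inherits(grid, "marsh_grid"), inherits(marsh, "marsh_geometry"))
  if (!length(marsh$zones)) stop("marsh has no zone polygons")
  cs <- attr(grid, "cell_size_m")
  zl <- zone_levels[zone_levels %in% names(marsh$zones)]
  idx <- which(grid$included)
  uncovered <- character(0)
  for (i in idx) {
    a <- vapply(zl, function(z)
      sum(vapply(marsh$zones[[z]], poly_rect_area, 0,
                 xmin = grid$x0[i], xmax = grid$x0[i] + cs,
                 ymin = grid$y0[i], ymax = grid$y0[i] + cs)), 0)
    if (max(a) <= 1e-9) {
      uncovered <- c(uncovered, grid$cell_id[i])
    } else {
      grid$zone[i] <- zl[which.max(a)]  # first max: nearer the sea wall
    }
  }
  if (length(uncovered))
    stop("included cell(s) with no habitat-zone coverage: ",
         paste(utils::head(uncovered, 10), collapse = ", "))
  grid
}

#' Cattle activity per grid cell
#'
#' The activity statistic is `H * (n_cw / N_w) / a_c`, with `H` the herd
#' size, `n_cw` the number of GPS fixes in cell `c` in window `w`, `N_w` the
#' total fixes landing in included cells in the window, and `a_c` the cell's
#' marsh area in hectares. It is the mean number of cattle present in the
#' cell over the window, per hectare. Fixes falling in excluded cells (or
#' off the grid) are dropped from both numerator and denominator and
#' reported.
#'
#' @param tracks A [track_set()] with week labels (see [assign_weeks()]),
#'   unless `window` is given.
#' @param grid A `marsh_grid` from [build_grid()].
#' @param weeks Optional vector of week indices to restrict to.
#' @param window Optional length-2 POSIXct/Date vector: pool all fixes with
#'   `window[1] <= t < window[2]` into a single surface.
#' @param pool If `TRUE`, pool the selected weeks into a single surface.
#' @return An `activity_grid`: list with `cells`, sparse `counts`
#'   (`cell_id, week, n, activity_ha`; `week` is `NA` when pooled),
#'   `week_totals` (`week, n_included, n_excluded`), `herd_size`, `pooled`.
#' @export
cattle_activity <- function(tracks, grid, weeks = NULL, window = NULL,
                            pool = FALSE) {
  stopifnot(inherits(tracks, "track_set"), inherits(grid, "marsh_grid"))
  f <- tracks$fixes
  if (!is.null(window)) {
    w0 <- as.POSIXct(window[1], tz = "UTC")
    w1 <- as.POSIXct(window[2], tz = "UTC")
    f <- f[f$timestamp >= w0 & f$timestamp < w1, , drop = FALSE]
    pool <- TRUE
  } else {
    if (is.null(f$week))
      stop("fixes carry no week labels; run assign_weeks() first ",
           "or supply `window`")
    if (!is.null(weeks)) f <- f[f$week %in% weeks, , drop = FALSE]
  }
  if (nrow(f) == 0) stop("no fixes in the requested window")
  loc <- locate_cells(grid, f$x_m, f$y_m)
  grp_all <- if (pool) rep("all", nrow(f)) else as.character(f$week)
  keep <- loc$included
  n_excl <- tapply(!keep, grp_all, sum)
  if (!any(keep)) stop("no fixes land in included grid cells")
  cid <- loc$cell_id[keep]
  grp <- grp_all[keep]
  tab <- as.data.frame(table(cell_id = cid, grp = grp),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  totals <- tapply(tab$Freq, tab$grp, sum)
  counts <- data.frame(
    cell_id = tab$cell_id,
    week = if (pool) NA_integer_ else as.integer(tab$grp),
    n = tab$Freq, stringsAsFactors = FALSE)
  N <- as.numeric(totals[tab$grp])
  area_ha <- grid$marsh_area_m2[match(counts$cell_id, grid$cell_id)] / 1e4
  counts$activity_ha <- tracks$herd_size * (counts$n / N) / area_ha
  week_totals <- data.frame(
    week = if (pool) NA_integer_ else as.integer(names(totals)),
    n_included = as.integer(totals),
    n_excluded = as.integer(n_excl[names(totals)]))
  week_totals$n_excluded[is.na(week_totals$n_excluded)] <- 0L
  if (any(week_totals$n_excluded > 0))
    message(sum(week_totals$n_excluded),
            " fix(es) in excluded cells dropped from activity totals")
  ord <- order(week_totals$week)
  structure(list(cells = grid, counts = counts,
                 week_totals = week_totals[ord, , drop = FALSE],
                 herd_size = tracks$herd_size, pooled = pool,
                 marsh_id = tracks$marsh_id),
            class = "activity_grid")
}

#' @export
print.activity_grid <- function(x, ...) {
  cat(sprintf("activity_grid %s: %d included cells, %s, herd %d\n",
              x$marsh_id %||% "?", sum(x$cells$included),
              if (x$pooled) "pooled window"
              else paste(nrow(x$week_totals), "weeks"),
              x$herd_size))
  invisible(x)
}

#' Per-zone weekly activity series
#'
#' Cattle activity aggregated to habitat zones: for zone `z` and week `w`,
#' `H * (n_zw / N_w) / area_ha(z)`, the mean cattle per hectare of the zone.
#' Weeks with fixes but none in a zone contribute explicit zeros.
#'
#' @param activity An `activity_grid` with zones assigned.
#' @return Data frame `week, zone, n, activity_ha`.
#' @export
zone_weekly_activity <- function(activity) {
  stopifnot(inherits(activity, "activity_grid"), !activity$pooled)
  cells <- activity$cells
  if (all(is.na(cells$zone))) stop("grid has no zone labels")
  zl <- zone_levels[zone_levels %in% unique(stats::na.omit(cells$zone))]
  zarea <- vapply(zl, function(z)
    sum(cells$marsh_area_m2[cells$included & cells$zone %in% z]) / 1e4, 0)
  counts <- activity$counts
  counts$zone <- cells$zone[match(counts$cell_id, cells$cell_id)]
  out <- expand.grid(week = activity$week_totals$week, zone = zl,
                     stringsAsFactors = FALSE)
  agg <- stats::aggregate(n ~ week + zone, data = counts, FUN = sum)
  m <- match(paste(out$week, out$zone), paste(agg$week, agg$zone))
  out$n <- ifelse(is.na(m), 0L, agg$n[m])
  Nw <- activity$week_totals$n_included[match(out$week,
                                              activity$week_totals$week)]
  out$activity_ha <- activity$herd_size * (out$n / Nw) /
    zarea[match(out$zone, zl)]
  out[order(out$week, match(out$zone, zone_levels)), , drop = FALSE]
}

#' Seasonal cattle density and livestock units
#'
#' @param herd_size Head of cattle.
#' @param marsh_area_ha Marsh area in hectares.
#' @param lsu_coefficient Livestock-unit coefficient for the stock class
#'   (0.8 for young cattle).
#' @return List of class `stocking_summary`: unrounded `scd_raw`/`lsu_raw`
#'   and `scd_per_ha`/`lsu_per_ha` rounded half-up to 2 decimals for
#'   reporting.
#' @export
seasonal_cattle_density <- function(herd_size, marsh_area_ha,
                                    lsu_coefficient = 0.8) {
  if (marsh_area_ha <= 0) stop("marsh_area_ha must be positive")
  if (herd_size <= 0) stop("herd_size must be positive")
  scd <- herd_size / marsh_area_ha
  lsu <- scd * lsu_coefficient
  structure(list(scd_raw = scd, lsu_raw = lsu,
                 scd_per_ha = round_half_up(scd, 2),
                 lsu_per_ha = round_half_up(lsu, 2),
                 lsu_coefficient = lsu_coefficient),
            class = "stocking_summary")
}

#' @export
print.stocking_summary <- function(x, ...) {
  cat(sprintf("SCD %.2f ha^-1, LSU %.2f ha^-1 (coefficient %.2f)\n",
              x$scd_per_ha, x$lsu_per_ha, x$lsu_coefficient))
  invisible(x)
}

#' Distance to the sea wall
#'
#' Euclidean distance from points (or grid-cell centroids) to the nearest
#' point on the sea-wall polyline.
#'
#' @param x Numeric x coordinates, or a `marsh_grid` (centroids are used).
#' @param y Numeric y coordinates (ignored when `x` is a grid).
#' @param seawall Sea-wall polyline matrix.
#' @return Numeric vector of distances in metres.
#' @export
distance_to_seawall <- function(x, y = NULL, seawall) {
  if (inherits(x, "marsh_grid")) {
    y <- x$cy
    x <- x$cx
  }
  dist_to_polyline(x, y, seawall)
}
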