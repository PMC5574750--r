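# Synthetic-data module: marsh geometry, herd GPS tracks, dummy-nest trials.
#
# The simulator defines the study conditions under which the pipeline is
# exercised: a rectangular marsh with the sea wall along one edge, habitat
# zones as distance bands from the wall, a biased correlated random walk for
# the herd with a hump-shaped seasonal range expansion, and Bernoulli disc
# trampling whose per-period probability is logistic in local cattle
# activity.

#' Simulation configuration
#'
#' Defaults emulate a 126-ha Wash-type marsh grazed by 39 young cattle from
#' mid May to late October, 4 GPS collars logging every 20 min, week 1 of the
#' shorebird season starting 14 April, and a saturating trampling
#' dose-response (24-day trampling probability near 0 without cattle and
#' near 1 above ~3 cattle/ha).
#'
#' @param marsh_area_ha Marsh area in hectares.
#' @param seawall_length_m Length of the sea wall (the marsh edge at x = 0).
#' @param zone_band_widths_m Named widths (m) of the four habitat bands,
#'   ordered by proximity to the sea wall (see [zone_levels]). The last band
#'   is extended to the seaward edge when the widths under-fill the marsh
#'   depth.
#' @param creek_density Expected creeks per hectare; total creek area is
#'   capped at 1% of the marsh area so the usable area stays within 1% of
#'   `marsh_area_ha`.
#' @param herd_size Number of cattle in the herd.
#' @param n_collars Number of GPS-collared cattle (1..herd_size).
#' @param fix_interval_min GPS logging interval in minutes.
#' @param season_weeks Number of 7-day season weeks.
#' @param week1_start_date First day of season week 1.
#' @param grazing_start_date,grazing_end_date Grazing window (inclusive
#'   dates).
#' @param attraction_point Water-trough location on the landward edge;
#'   default mid sea wall.
#' @param expansion_peak_week Week of maximum range expansion.
#' @param range_min_m,range_max_m Seasonal range scale (m) at the season
#'   edges and at the expansion peak.
#' @param range_sigma_weeks Width (weeks) of the Gaussian range hump.
#' @param home_pull Ornstein-Uhlenbeck pull toward the attraction point per
#'   step (0..1).
#' @param cohesion Pull toward the herd centroid per step (0..1).
#' @param persistence Autocorrelation of step displacements (0..1).
#' @param dropout Optional named list collar id -> last active date,
#'   emulating collar battery failure.
#' @param tide_pulse If `TRUE`, adds a periodic extra pull toward the sea
#'   wall (off by default; tides are not part of the core model).
#' @param tide_period_hours,tide_strength Tidal pulse parameters.
#' @param true_dose_response Named vector `c(beta0=, beta1=)`: logit-scale
#'   intercept and slope (per cattle/ha) of the per-period trampling
#'   probability used as simulation ground truth; `beta1 > 0`.
#' @param period_days Length of a dummy-nest exposure period in days.
#' @param rng_seed Integer seed; every stochastic operation derives its
#'   stream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(marsh_area_ha = 126,
                       seawall_length_m = 1800,
                       zone_band_widths_m = c(non_saltmarsh = 50,
                                              mid_marsh_redshank = 250,
                                              elytrigia_redshank = 100,
                                              non_redshank = 300),
                       creek_density = 0.02,
                       herd_size = 39,
                       n_collars = 4,
                       fix_interval_min = 20,
                       season_weeks = 28,
                       week1_start_date = as.Date("2013-04-14"),
                       grazing_start_date = as.Date("2013-05-19"),
                       grazing_end_date = as.Date("2013-10-26"),
                       attraction_point = NULL,
                       expansion_peak_week = 19,
                       range_min_m = 120,
                       range_max_m = 350,
                       range_sigma_weeks = 6,
                       home_pull = 0.15,
                       cohesion = 0.2,
                       persistence = 0.3,
                       dropout = NULL,
                       tide_pulse = FALSE,
                       tide_period_hours = 12.42,
                       tide_strength = 0.2,
                       true_dose_response = c(beta0 = -4, beta1 = 2.2),
                       period_days = 14,
                       rng_seed = 1L) {
  cfg <- as.list(environment())
  cfg$week1_start_date <- as.Date(week1_start_date)
  cfg$grazing_start_date <- as.Date(grazing_start_date)
  cfg$grazing_end_date <- as.Date(grazing_end_date)
  if (is.null(names(cfg$zone_band_widths_m)))
    names(cfg$zone_band_widths_m) <- zone_levels
  if (is.null(attraction_point))
    cfg$attraction_point <- c(x = 0, y = seawall_length_m / 2)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config`.
#' @return `cfg`, invisibly; stops with an informative error when invalid.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(cfg$marsh_area_ha > 0, cfg$seawall_length_m > 0,
            cfg$fix_interval_min > 0, cfg$season_weeks >= 1,
            cfg$herd_size >= 1)
  if (length(cfg$zone_band_widths_m) != 4 || any(cfg$zone_band_widths_m <= 0))
    stop("zone_band_widths_m must be 4 positive widths")
  if (!setequal(names(cfg$zone_band_widths_m), zone_levels))
    stop("zone_band_widths_m names must be: ",
         paste(zone_levels, collapse = ", "))
  if (cfg$n_collars < 1 || cfg$n_collars > cfg$herd_size)
    stop("n_collars must be in [1, herd_size]")
  if (cfg$creek_density < 0) stop("creek_density must be >= 0")
  tdr <- cfg$true_dose_response
  if (!all(c("beta0", "beta1") %in% names(tdr)) || tdr[["beta1"]] < 0)
    stop("true_dose_response must have beta0 and beta1 >= 0")
  if (cfg$grazing_end_date <= cfg$grazing_start_date)
    stop("grazing_end_date must be after grazing_start_date")
  # band feasibility against marsh depth
  depth <- cfg$marsh_area_ha * 1e4 / cfg$seawall_length_m
  w <- cfg$zone_band_widths_m[zone_levels]
  cum <- cumsum(w)
  bad <- which(cum > depth + 1e-9)
  if (length(bad))
    stop(sprintf("zone band '%s' exceeds the marsh depth (%.1f m): bands end at %.1f m",
                 zone_levels[bad[1]], depth, cum[bad[1]]))
  invisible(cfg)
}

#' Generate synthetic marsh geometry
#'
#' A rectangular marsh of area `marsh_area_ha` with the sea wall along the
#' x = 0 edge, four habitat-zone bands at increasing distance from the wall,
#' and creek polygons (thin rectangles running seaward) subtracted from the
#' usable area. The seaward-most band is extended to the seaward edge when
#' the band widths under-fill the marsh depth.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (default derived from `config$rng_seed`).
#' @return A [marsh_geometry()].
#' @export
generate_marsh <- function(config, seed = config$rng_seed) {
  validate_sim_config(config)
  area_m2 <- config$marsh_area_ha * 1e4
  L <- config$seawall_length_m
  depth <- area_m2 / L
  boundary <- rect_poly(0, depth, 0, L)
  seawall <- cbind(x = c(0, 0), y = c(0, L))

  w <- config$zone_band_widths_m[zone_levels]
  edges <- c(0, cumsum(w))
  edges[5] <- depth  # stretch the seaward band to the edge
  band_rects <- lapply(1:4, function(i) c(edges[i], edges[i + 1], 0, L))
  names(band_rects) <- zone_levels

  creeks <- list()
  creek_rects <- list()
  n_creek <- round(config$creek_density * config$marsh_area_ha)
  if (n_creek > 0) {
    with_seed(seed, {
      cap <- 0.01 * area_m2
      total <- 0
      tries <- 0
      while (length(creeks) < n_creek && tries < 50 * n_creek) {
        tries <- tries + 1
        cw <- stats::runif(1, 4, 8)                       # across-creek width
        cl <- stats::runif(1, 80, min(250, 0.6 * depth))  # seaward length
        x0 <- stats::runif(1, min(0.15 * depth, depth - cl),
                           max(0.15 * depth, depth - cl))
        y0 <- stats::runif(1, 0, L - cw)
        cand <- c(x0, x0 + cl, y0, y0 + cw)
        overlaps <- any(vapply(creek_rects, function(r) {
          cand[1] < r[2] + 1 && r[1] < cand[2] + 1 &&
            cand[3] < r[4] + 1 && r[3] < cand[4] + 1
        }, logical(1)))
        if (overlaps) next
        a <- (cand[2] - cand[1]) * (cand[4] - cand[3])
        if (total + a > cap) break
        total <- total + a
        creek_rects[[length(creek_rects) + 1L]] <- cand
        creeks[[length(creeks) + 1L]] <-
          rect_poly(cand[1], cand[2], cand[3], cand[4])
      }
    })
  }

  zones <- lapply(band_rects, function(b) {
    lapply(rect_subtract(b, creek_rects),
           function(r) rect_poly(r[1], r[2], r[3], r[4]))
  })

  m <- marsh_geometry(boundary, seawall, creeks, zones, marsh_id = "SYN")
  m$depth_m <- depth
  m$length_m <- L
  m$seed <- seed
  m
}

# seasonal range scale (m) for a vector of week indices
.range_scale <- function(week, config) {
  config$range_min_m + (config$range_max_m - config$range_min_m) *
    exp(-0.5 * ((week - config$expansion_peak_week) /
                  config$range_sigma_weeks)^2)
}

# reflect values into [lo, hi]
.fold <- function(v, lo, hi) {
  rng <- hi - lo
  v <- (v - lo) %% (2 * rng)
  v <- ifelse(v > rng, 2 * rng - v, v)
  v + lo
}

# push points out of creek rectangles (nearest edge + 1 cm)
.nudge_out_of_creeks <- function(xy, creek_rects) {
  for (r in creek_rects) {
    inside <- xy[, 1] > r[1] & xy[, 1] < r[2] &
      xy[, 2] > r[3] & xy[, 2] < r[4]
    if (!any(inside)) next
    for (i in which(inside)) {
      d <- c(xy[i, 1] - r[1], r[2] - xy[i, 1], xy[i, 2] - r[3], r[4] - xy[i, 2])
      k <- which.min(d)
      if (k == 1) xy[i, 1] <- r[1] - 0.01
      else if (k == 2) xy[i, 1] <- r[2] + 0.01
      else if (k == 3) xy[i, 2] <- r[3] - 0.01
      else xy[i, 2] <- r[4] + 0.01
    }
  }
  xy
}

#' Simulate herd GPS tracks
#'
#' A biased correlated random walk: each collar is pulled toward the water
#' trough on the sea wall (Ornstein-Uhlenbeck home pull), toward the herd
#' centroid (cohesion), and keeps some directional persistence. The step
#' noise scales with a seasonal range parameter that rises to
#' `expansion_peak_week` and falls again (Gaussian hump), producing the
#' early-season concentration near the sea wall and the mid-season expansion.
#' Walkers are reflected at the marsh boundary and nudged off creeks.
#'
#' @param marsh A [marsh_geometry()] from [generate_marsh()].
#' @param config A [sim_config()].
#' @param seed RNG seed (default `config$rng_seed + 1`).
#' @return A [track_set()] with one fix per collar per `fix_interval_min`
#'   over the grazing window.
#' @export
simulate_herd_tracks <- function(marsh, config, seed = config$rng_seed + 1L) {
  validate_sim_config(config)
  depth <- marsh$depth_m %||% max(marsh$boundary[, 1])
  L <- marsh$length_m %||% max(marsh$boundary[, 2])
  t0 <- as.POSIXct(paste(config$grazing_start_date, "00:00:00"), tz = "UTC")
  t_end <- as.POSIXct(paste(config$grazing_end_date + 1, "00:00:00"),
                      tz = "UTC")
  total_min <- as.numeric(difftime(t_end, t0, units = "mins"))
  n_steps <- floor(total_min / config$fix_interval_min)
  times <- t0 + (seq_len(n_steps) - 1) * config$fix_interval_min * 60
  wk1 <- as.POSIXct(paste(config$week1_start_date, "00:00:00"), tz = "UTC")
  weeks <- 1 + floor(as.numeric(difftime(times, wk1, units = "days")) / 7)
  rng <- .range_scale(weeks, config)
  k <- config$home_pull
  sig <- (rng / 2) * sqrt(max(2 * k - k^2, 1e-8))
  nc <- config$n_collars
  A <- config$attraction_point
  creek_rects <- lapply(marsh$creeks, .poly_bbox)

  xs <- matrix(NA_real_, n_steps, nc)
  ys <- matrix(NA_real_, n_steps, nc)
  with_seed(seed, {
    pos <- cbind(A[1] + abs(stats::rnorm(nc, 0, sig[1] + 1e-12)),
                 A[2] + stats::rnorm(nc, 0, sig[1] + 1e-12))
    pos[, 1] <- .fold(pos[, 1], 0, depth)
    pos[, 2] <- .fold(pos[, 2], 0, L)
    pos <- .nudge_out_of_creeks(pos, creek_rects)
    disp <- matrix(0, nc, 2)
    for (s in seq_len(n_steps)) {
      cbar <- colMeans(pos)
      pull <- k
      if (config$tide_pulse) {
        phase <- as.numeric(difftime(times[s], t0, units = "hours")) /
          config$tide_period_hours
        pull <- k + config$tide_strength * (1 + cos(2 * pi * phase)) / 2
      }
      mu <- pull * cbind(A[1] - pos[, 1], A[2] - pos[, 2]) +
        config$cohesion * cbind(cbar[1] - pos[, 1], cbar[2] - pos[, 2]) +
        config$persistence * disp
      newpos <- pos + mu + matrix(stats::rnorm(2 * nc, 0, sig[s]), nc, 2)
      newpos[, 1] <- .fold(newpos[, 1], 0, depth)
      newpos[, 2] <- .fold(newpos[, 2], 0, L)
      newpos <- .nudge_out_of_creeks(newpos, creek_rects)
      disp <- newpos - pos
      pos <- newpos
      xs[s, ] <- pos[, 1]
      ys[s, ] <- pos[, 2]
    }
  })

  collar_ids <- sprintf("C%02d", seq_len(nc))
  fixes <- data.frame(
    collar_id = rep(collar_ids, each = n_steps),
    timestamp = rep(times, nc),
    x_m = as.vector(xs),
    y_m = as.vector(ys),
    stringsAsFactors = FALSE)

  if (!is.null(config$dropout)) {
    keep <- rep(TRUE, nrow(fixes))
    for (cid in names(config$dropout)) {
      last <- as.Date(config$dropout[[cid]])
      keep <- keep & !(fixes$collar_id == cid &
                         as.Date(fixes$timestamp, tz = "UTC") > last)
    }
    fixes <- fixes[keep, , drop = FALSE]
  }

  track_set(fixes, herd_size = config$herd_size,
            marsh_id = marsh$marsh_id %||% "SYN",
            grazing_start = config$grazing_start_date,
            grazing_end = config$grazing_end_date,
            seed = seed)
}

#' Stratified random dummy-nest plot layout
#'
#' Samples plot centres stratified over distance-to-seawall bands so the
#' layout covers the full range of distances (and thereby all habitat
#' zones), with a minimum spacing between plots.
#'
#' @param marsh A [marsh_geometry()].
#' @param n_plots Number of plots.
#' @param min_dist_m Minimum distance between plot centres.
#' @param n_strata Number of equal-width distance strata.
#' @param seed RNG seed.
#' @return Data frame `plot_id, x_m, y_m`.
#' @export
sample_plot_layout <- function(marsh, n_plots = 30, min_dist_m = 50,
                               n_strata = 6, seed = 1L) {
  depth <- marsh$depth_m %||% max(marsh$boundary[, 1])
  L <- marsh$length_m %||% max(marsh$boundary[, 2])
  creek_rects <- lapply(marsh$creeks, .poly_bbox)
  per <- ceiling(n_plots / n_strata)
  pts <- matrix(numeric(0), 0, 2)
  with_seed(seed, {
    for (s in seq_len(n_strata)) {
      lo <- (s - 1) * depth / n_strata
      hi <- s * depth / n_strata
      got <- 0
      tries <- 0
      while (got < per && nrow(pts) < n_plots && tries < 500) {
        tries <- tries + 1
        p <- c(stats::runif(1, lo + 5, hi - 5), stats::runif(1, 5, L - 5))
        in_creek <- any(vapply(creek_rects, function(r)
          p[1] > r[1] && p[1] < r[2] && p[2] > r[3] && p[2] < r[4],
          logical(1)))
        if (in_creek) next
        if (nrow(pts) &&
            min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) < min_dist_m)
          next
        pts <- rbind(pts, p)
        got <- got + 1
      }
    }
  })
  data.frame(plot_id = sprintf("P%02d", seq_len(nrow(pts))),
             x_m = pts[, 1], y_m = pts[, 2], stringsAsFactors = FALSE)
}

#' Ground-truth dose-response parameters
#'
#' Logistic per-period trampling probability used as simulation ground
#' truth: `logit(p_period) = beta0 + beta1 * activity`.
#'
#' @param beta0 Logit intercept.
#' @param beta1 Logit slope per unit cattle activity (>= 0).
#' @param horizon_days Period length in days.
#' @return A list of class `true_dose_response`.
#' @export
true_dose_response <- function(beta0 = -4, beta1 = 2.2, horizon_days = 14) {
  if (beta1 < 0) stop("beta1 must be >= 0 (risk non-decreasing in activity)")
  structure(list(beta0 = beta0, beta1 = beta1, horizon_days = horizon_days),
            class = "true_dose_response")
}

#' Simulate dummy-nest trampling trials
#'
#' Each plot holds `n_discs` clay-pigeon discs for two consecutive exposure
#' periods; discs broken in period 1 are replaced, so both periods have the
#' full complement at risk. Each disc is broken independently with
#' probability `plogis(beta0 + beta1 * activity)` where activity is the
#' cattle activity (cattle/ha) of the grid cell containing the plot centre
#' over the exposure window.
#'
#' @param activity An [cattle_activity()] surface pooled over the exposure
#'   window (`pool = TRUE`).
#' @param plots Data frame `plot_id, x_m, y_m` of plot centres.
#' @param truth A [true_dose_response()].
#' @param seed RNG seed.
#' @param n_discs Discs per plot.
#' @return A list of class `trampling_trials` with elements `trials`
#'   (plot-level: `plot_id, x_m, y_m, cell_id, activity_ha, n_discs,
#'   broken_p1, broken_p2`) and `discs` (disc-level long table:
#'   `plot_id, disc_id, period, broken`).
#' @export
simulate_trampling_trials <- function(activity, plots, truth, seed = 1L,
                                      n_discs = 9L) {
  stopifnot(inherits(activity, "activity_grid"), activity$pooled,
            inherits(truth, "true_dose_response"))
  loc <- locate_cells(activity$cells, plots$x_m, plots$y_m)
  ok <- !is.na(loc$cell_id) & loc$included
  if (any(!ok)) {
    warning(sum(!ok), " plot(s) fall outside included grid cells and were ",
            "excluded: ", paste(plots$plot_id[!ok], collapse = ", "))
  }
  plots <- plots[ok, , drop = FALSE]
  loc <- loc[ok, , drop = FALSE]
  act <- activity$counts$activity_ha[match(loc$cell_id,
                                           activity$counts$cell_id)]
  act[is.na(act)] <- 0
  p <- invlogit(truth$beta0 + truth$beta1 * act)
  n <- nrow(plots)
  with_seed(seed, {
    b1 <- stats::rbinom(n, n_discs, p)
    b2 <- stats::rbinom(n, n_discs, p)
  })
  trials <- data.frame(plot_id = plots$plot_id, x_m = plots$x_m,
                       y_m = plots$y_m, cell_id = loc$cell_id,
                       activity_ha = act, n_discs = n_discs,
                       broken_p1 = b1, broken_p2 = b2,
                       stringsAsFactors = FALSE)
  discs <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(plot_id = trials$plot_id[i],
               disc_id = rep(sprintf("D%d", seq_len(n_discs)), 2),
               period = rep(1:2, each = n_discs),
               broken = c(as.integer(seq_len(n_discs) <= b1[i]),
                          as.integer(seq_len(n_discs) <= b2[i])),
               stringsAsFactors = FALSE)
  }))
  structure(list(trials = trials, discs = discs, seed = seed,
                 period_days = truth$horizon_days),
            class = "trampling_trials")
}
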