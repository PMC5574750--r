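# Shared fixtures, all built in code.

# 9-ha square marsh (300 x 300 m), 36 full 50-m cells, short grazing window
tiny_config <- function(...) {
  defaults <- list(
    marsh_area_ha = 9, seawall_length_m = 300,
    zone_band_widths_m = c(non_saltmarsh = 50, mid_marsh_redshank = 100,
                           elytrigia_redshank = 50, non_redshank = 100),
    creek_density = 0, herd_size = 10, n_collars = 2, fix_interval_min = 60,
    grazing_start_date = as.Date("2013-05-19"),
    grazing_end_date = as.Date("2013-07-27"),
    expansion_peak_week = 10, range_min_m = 30, range_max_m = 100,
    range_sigma_weeks = 3)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# bare square marsh with a single all-covering zone
square_marsh <- function(side = 100, zone = "mid_marsh_redshank") {
  zones <- stats::setNames(list(list(rect_poly(0, side, 0, side))), zone)
  m <- marsh_geometry(rect_poly(0, side, 0, side),
                      cbind(x = c(0, 0), y = c(0, side)),
                      zones = zones, marsh_id = "SQ")
  m$depth_m <- side
  m$length_m <- side
  m
}

# track_set from bare coordinates, 10-min timestamps starting at week 1
make_tracks <- function(x, y, herd_size = 10, collar = "C01",
                        start = as.POSIXct("2013-04-14 00:00:00", tz = "UTC")) {
  n <- length(x)
  track_set(data.frame(collar_id = rep(collar, length.out = n),
                       timestamp = start + seq_len(n) * 600,
                       x_m = x, y_m = y, stringsAsFactors = FALSE),
            herd_size = herd_size)
}

# uniform random fixes on a square marsh, all in week 1
uniform_tracks <- function(n, side = 100, herd_size = 10, seed = 1) {
  set.seed(seed)
  make_tracks(runif(n, 0, side), runif(n, 0, side), herd_size = herd_size)
}

# distance oracle: per-segment 1-D minimisation, independent of the
# projection formula used by dist_to_polyline
dist_oracle <- function(x, y, polyline) {
  vapply(seq_along(x), function(i) {
    best <- Inf
    for (s in seq_len(nrow(polyline) - 1)) {
      a <- polyline[s, ]; b <- polyline[s + 1, ]
      f <- function(t) sqrt((x[i] - (a[1] + t * (b[1] - a[1])))^2 +
                              (y[i] - (a[2] + t * (b[2] - a[2])))^2)
      o <- stats::optimize(f, c(0, 1), tol = 1e-12)$objective
      best <- min(best, f(0), f(1), o)
    }
    best
  }, numeric(1))
}
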