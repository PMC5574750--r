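# 1000 x 500 m marsh: 200 full 50-m cells, three cell-aligned zones
make_metric_setup <- function() {
  m <- marsh_geometry(rect_poly(0, 1000, 0, 500),
                      cbind(x = c(0, 0), y = c(0, 500)),
                      zones = list(
                        non_saltmarsh = list(rect_poly(0, 100, 0, 500)),
                        mid_marsh_redshank = list(rect_poly(100, 400, 0, 500)),
                        non_redshank = list(rect_poly(400, 1000, 0, 500))))
  g <- assign_zones(build_grid(m), m)
  list(marsh = m, grid = g)
}

test_that("CA100 is the visited fraction of included cells", {
  s <- make_metric_setup()
  # 5 visited cells out of 200
  xy <- cbind(c(25, 125, 225, 325, 425), c(25, 25, 25, 25, 25))
  tr <- assign_weeks(make_tracks(xy[, 1], xy[, 2], herd_size = 10),
                     season_calendar())
  ag <- cattle_activity(tr, s$grid)
  expect_equal(ca100(ag, 1), 2.5)
  expect_true(is.na(ca100(ag, 5)))  # no fixes that week: missing, not zero
  # all cells visited -> 100
  centers <- expand.grid(x = seq(25, 975, 50), y = seq(25, 475, 50))
  tr2 <- assign_weeks(make_tracks(centers$x, centers$y, herd_size = 10),
                      season_calendar())
  ag2 <- cattle_activity(tr2, s$grid)
  expect_equal(ca100(ag2, 1), 100)
})

test_that("CA100 equals the greedy minimal covering set", {
  s <- make_metric_setup()
  tr <- assign_weeks(uniform_tracks(300, side = 500, seed = 8),
                     season_calendar())
  ag <- cattle_activity(tr, s$grid)
  for (w in unique(ag$counts$week)) {
    cnt <- ag$counts[ag$counts$week == w, ]
    # greedy: add cells in decreasing count order until all fixes covered
    ord <- order(cnt$n, decreasing = TRUE)
    need <- which(cumsum(cnt$n[ord]) >= sum(cnt$n))[1]
    expect_equal(ca100(ag, w), 100 * need / sum(s$grid$included))
  }
})

test_that("never-visited fraction complements the union of weekly visits", {
  s <- make_metric_setup()
  tr <- assign_weeks(uniform_tracks(250, side = 400, seed = 9),
                     season_calendar())
  ag <- cattle_activity(tr, s$grid)
  visited_union <- unique(ag$counts$cell_id)
  expect_equal(never_visited_fraction(ag),
               100 * (1 - length(visited_union) / sum(s$grid$included)))
  # single-cell season
  tr1 <- assign_weeks(make_tracks(rep(25, 10), rep(25, 10), herd_size = 10),
                      season_calendar())
  expect_equal(never_visited_fraction(cattle_activity(tr1, s$grid)),
               100 * 199 / 200)
})

test_that("zone activity shares split fixes by labelled zone", {
  s <- make_metric_setup()
  # 30 fixes in non_saltmarsh, 10 in mid_marsh (3:1), none elsewhere
  x <- c(runif(30, 5, 95), runif(10, 105, 395))
  y <- runif(40, 5, 495)
  tr <- assign_weeks(make_tracks(x, y, herd_size = 10), season_calendar())
  ag <- cattle_activity(tr, s$grid)
  sh <- zone_activity_share(ag, week = 1)
  expect_equal(sh$share_pct[sh$zone == "non_saltmarsh"], 75)
  expect_equal(sh$share_pct[sh$zone == "mid_marsh_redshank"], 25)
  expect_equal(sh$share_pct[sh$zone == "non_redshank"], 0)
  expect_equal(sum(sh$share_pct), 100, tolerance = 1e-9)
  # area shares reflect zone footprints (zones aligned to cell boundaries)
  expect_equal(sh$area_pct, c(10, 30, 60), tolerance = 1e-9)
  # polygon oracle: share equals direct point-in-zone-polygon counting
  for (z in sh$zone) {
    inside <- points_in_poly(x, y, s$marsh$zones[[z]][[1]])
    expect_equal(sh$share_pct[sh$zone == z], 100 * mean(inside))
  }
})

test_that("p95 distance uses type-7 interpolation and behaves geometrically", {
  sw <- cbind(x = c(0, 0), y = c(0, 500))
  tr <- assign_weeks(make_tracks(0:100, rep(50, 101), herd_size = 10),
                     season_calendar())
  expect_equal(as.numeric(p95_distance(tr, sw, 1)), 95)
  tr2 <- assign_weeks(make_tracks(rep(500, 30), rep(50, 30), herd_size = 10),
                      season_calendar())
  expect_equal(as.numeric(p95_distance(tr2, sw, 1)), 500)
  # translation equivariance
  tr3 <- tr
  tr3$fixes$x_m <- tr3$fixes$x_m + 100
  expect_equal(as.numeric(p95_distance(tr3, sw, 1)), 195)
  # order bounds on random data
  set.seed(61)
  trr <- assign_weeks(make_tracks(runif(150, 0, 900), runif(150, 0, 500),
                                  herd_size = 10),
                      season_calendar())
  d <- dist_to_polyline(trr$fixes$x_m, trr$fixes$y_m, sw)
  p <- as.numeric(p95_distance(trr, sw, 1))
  expect_lte(p, max(d))
  expect_gte(p, median(d))
  # low-n flag
  expect_true(attr(p95_distance(tr2, sw, 1, min_n = 50), "low_n"))
})

test_that("CA100 never decreases when fixes are added to a week", {
  s <- make_metric_setup()
  set.seed(71)
  x <- runif(120, 0, 800)
  y <- runif(120, 0, 500)
  vals <- vapply(c(30, 60, 90, 120), function(k) {
    tr <- assign_weeks(make_tracks(x[1:k], y[1:k], herd_size = 10),
                       season_calendar())
    ca100(cattle_activity(tr, s$grid), 1)
  }, 0)
  expect_true(all(diff(vals) >= 0))
})
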