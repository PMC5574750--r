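test_that("period-to-daily-to-incubation algebra matches closed forms", {
  expect_equal(daily_probability(0), 0)
  expect_equal(daily_probability(1), 1)
  # independent oracle via exp/log rather than ^
  expect_equal(daily_probability(0.5, 14), 1 - exp(log(0.5) / 14),
               tolerance = 1e-15)
  expect_equal(round(daily_probability(0.5, 14), 4), 0.0483)
  expect_equal(incubation_probability(0), 0)
  expect_equal(incubation_probability(daily_probability(0.5, 14), 24),
               1 - exp(24 / 14 * log(0.5)), tolerance = 1e-15)
  expect_equal(incubation_probability(daily_probability(0.5, 14), 24),
               0.6952, tolerance = 5e-4)
  # round trip with equal day counts is the identity
  p <- seq(0.1, 0.9, 0.1)
  expect_equal(incubation_probability(daily_probability(p, 14), 14), p,
               tolerance = 1e-12)
  expect_error(daily_probability(1.2), "0, 1")
  expect_error(incubation_probability(-0.1), "0, 1")
})

test_that("probability conversions are monotone in dose and duration", {
  p <- seq(0.05, 0.95, 0.05)
  expect_true(all(diff(daily_probability(p, 14)) > 0))
  expect_true(all(daily_probability(0.5, 7) > daily_probability(0.5, 14)))
  d <- seq(0.01, 0.2, 0.01)
  expect_true(all(diff(incubation_probability(d, 24)) > 0))
  expect_true(all(incubation_probability(d, 24) >= d))
})

test_that("plot probabilities combine the two periods as documented", {
  pp <- plot_probabilities(c(0, 9, 3), c(0, 9, 6))
  expect_equal(pp$p24[1], 0)
  expect_equal(pp$p24[2], 1)
  d1 <- 1 - (2 / 3)^(1 / 14)
  d2 <- 1 - (1 / 3)^(1 / 14)
  expect_equal(pp$p24[3], 1 - (1 - (d1 + d2) / 2)^24, tolerance = 1e-12)
  expect_error(plot_probabilities(10, 0), "n_discs")
})

# build plot-level trials directly from a known logistic period-level truth
sim_trials_df <- function(activities, beta0, beta1, n_discs = 9) {
  p <- plogis(beta0 + beta1 * activities)
  data.frame(plot_id = sprintf("P%03d", seq_along(activities)),
             activity_ha = activities, n_discs = n_discs,
             broken_p1 = rbinom(length(p), n_discs, p),
             broken_p2 = rbinom(length(p), n_discs, p))
}

truth_p24 <- function(a, beta0, beta1, period = 14, incub = 24) {
  pp <- plogis(beta0 + beta1 * a)
  incubation_probability(daily_probability(pp, period), incub)
}

test_that("null trials predict near-zero risk everywhere", {
  set.seed(201)
  d <- sim_trials_df(rep(0, 30), beta0 = -1e6, beta1 = 0)
  expect_warning(dr <- fit_dose_response(d), "intercept-only")
  expect_true(dr$degenerate)
  expect_lt(suppressWarnings(predict(dr, 0)), 0.05)
})

test_that("a saturating truth is matched: ~0 at no cattle, ~1 above 3 ha^-1", {
  set.seed(202)
  acts <- rep(c(0, 0.25, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4), each = 6)
  d <- sim_trials_df(acts, beta0 = -4, beta1 = 3)
  dr <- fit_dose_response(d)
  expect_lt(predict(dr, 0), 0.1)
  expect_gt(predict(dr, 3), 0.99)
  # predictions stay probabilities over the mapped activity range
  curve <- dose_response_curve(dr, 0, 12, 0.05)
  expect_true(all(curve$p24 >= 0 & curve$p24 <= 1))
  expect_true(all(curve$lo <= curve$p24 & curve$p24 <= curve$hi))
  # clamping beyond the fitted range warns
  expect_warning(predict(dr, 11), "clamped")
})

test_that("period-level fitting agrees with nest-level on strong gradients", {
  set.seed(203)
  acts <- rep(c(0, 0.5, 1, 2, 3, 4), each = 8)
  d <- sim_trials_df(acts, beta0 = -3, beta1 = 1.5)
  dr_n <- fit_dose_response(d, level = "nest")
  dr_p <- fit_dose_response(d, level = "period")
  a <- c(0.5, 1, 2, 3)
  expect_equal(predict(dr_n, a), predict(dr_p, a), tolerance = 0.12)
})

test_that("dose-response recovery: truth lies in the Monte-Carlo band", {
  set.seed(204)
  beta0 <- -3; beta1 <- 1.5
  probes <- c(0, 1, 2, 4)
  acts <- rep(c(0, 0.5, 1, 2, 3, 4), each = 5)  # 30 plots
  preds <- replicate(60, {
    d <- sim_trials_df(acts, beta0, beta1)
    suppressWarnings(predict(fit_dose_response(d), probes))
  })
  lo <- apply(preds, 1, quantile, 0.025)
  hi <- apply(preds, 1, quantile, 0.975)
  tru <- truth_p24(probes, beta0, beta1)
  expect_true(all(tru >= lo & tru <= hi))
})

test_that("quadrupling the plots shrinks the integrated error", {
  set.seed(205)
  beta0 <- -3; beta1 <- 1.5
  grid_a <- seq(0, 4, 0.1)
  tru <- truth_p24(grid_a, beta0, beta1)
  iae <- function(n_per) {
    acts <- rep(c(0, 0.5, 1, 2, 3, 4), each = n_per)
    d <- sim_trials_df(acts, beta0, beta1)
    mean(abs(suppressWarnings(predict(fit_dose_response(d), grid_a)) - tru))
  }
  iae30 <- replicate(40, iae(5))
  iae120 <- replicate(40, iae(20))
  expect_lt(mean(iae120), 0.85 * mean(iae30))
})

test_that("risk maps transport activity ordering through a monotone model", {
  set.seed(206)
  m <- square_marsh(300)
  g <- build_grid(m)
  tr <- uniform_tracks(400, side = 300, herd_size = 20, seed = 6)
  act <- cattle_activity(tr, g, window = c(min(tr$fixes$timestamp),
                                           max(tr$fixes$timestamp) + 1))
  acts <- rep(c(0, 0.5, 1, 2, 3, 4), each = 6)
  d <- sim_trials_df(acts, beta0 = -4, beta1 = 2.2)
  dr <- fit_dose_response(d)
  risk <- predict_risk_map(dr, act)
  expect_equal(nrow(risk), sum(g$included))
  expect_true(all(risk$p24 >= 0 & risk$p24 <= 1))
  ord <- order(risk$activity_ha)
  expect_true(all(diff(risk$p24[ord]) >= -1e-9))
  # zero-activity cells inherit the near-zero baseline
  expect_true(all(risk$p24[risk$activity_ha == 0] < 0.1))
})

test_that("Moran's I screen separates clustered from exchangeable residuals", {
  set.seed(207)
  n <- 40
  x <- runif(n, 0, 100); y <- runif(n, 0, 100)
  clustered <- x / 50 + rnorm(n, 0, 0.05)
  ms <- moran_screen(clustered, x, y, seed = 1)
  expect_lt(ms$p_value, 0.05)
  noise <- rnorm(n)
  ms2 <- moran_screen(noise, x, y, seed = 1)
  expect_gt(ms2$p_value, 0.01)
})
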