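# simulate a 4-marsh x 28-week panel with AR(1) errors
sim_panel <- function(phi = 0, sd = 1, beta_week = 0, beta_week2 = 0,
                      marsh_effects = c(0, 0, 0, 0), bw_int = c(0, 0, 0, 0),
                      n_weeks = 28) {
  marshes <- LETTERS[1:4]
  do.call(rbind, lapply(seq_along(marshes), function(i) {
    e <- if (phi == 0) rnorm(n_weeks, 0, sd)
    else as.numeric(arima.sim(list(ar = phi), n_weeks,
                              sd = sd * sqrt(1 - phi^2)))
    week <- seq_len(n_weeks)
    data.frame(marsh = marshes[i], week = week,
               y = 10 + marsh_effects[i] + beta_week * week +
                 beta_week2 * week^2 + bw_int[i] * week + e,
               stringsAsFactors = FALSE)
  }))
}

test_that("without correlation the GLS fit reduces to OLS", {
  set.seed(101)
  d <- sim_panel(phi = 0, beta_week = 0.3)
  f <- y ~ marsh + week + I(week^2)
  fit <- fit_gls_ar1(f, d, correlation = FALSE)
  ols <- lm(f, data = d)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-6)
  expect_true(is.na(fit$phi))
  # on iid data the estimated AR(1) coefficient is near zero
  fit2 <- fit_gls_ar1(f, d, correlation = TRUE)
  expect_lt(abs(fit2$phi), 0.3)
})

test_that("the AR(1) coefficient is recovered from autocorrelated panels", {
  set.seed(102)
  phis <- replicate(60, {
    d <- sim_panel(phi = 0.6, beta_week = 0.2)
    fit_gls_ar1(y ~ marsh + week, d)$phi
  })
  expect_gt(mean(phis), 0.45)
  expect_lt(mean(phis), 0.70)
})

test_that("sequential term tables carry df, F and p for every term", {
  set.seed(103)
  d <- sim_panel(phi = 0.3, beta_week = 0.5,
                 marsh_effects = c(0, 2, 4, 6))
  fit <- fit_gls_ar1(y ~ marsh + week + I(week^2), d, transform = "identity")
  tt <- fit$term_table
  expect_equal(tt$term, c("marsh", "week", "I(week^2)"))
  expect_equal(tt$df, c(3, 1, 1))
  expect_true(all(tt$p >= 0 & tt$p <= 1))
  expect_true(all(tt$res_df > 0))
  expect_lt(tt$p[1], 0.001)  # strong marsh effect detected
})

test_that("a constant response degrades gracefully", {
  d <- sim_panel()
  d$y <- 5
  fit <- fit_gls_ar1(y ~ marsh + week, d)
  expect_true(fit$degenerate)
  expect_true(all(is.na(fit$term_table$p)))
  expect_equal(unname(fit$coefficients[1]), 5)
})

test_that("backward elimination respects marginality and terminates", {
  set.seed(104)
  # strong marsh, week, week2 and marsh:week structure; no marsh:week2
  d <- sim_panel(phi = 0.3, beta_week = 1.2, beta_week2 = -0.04,
                 marsh_effects = c(0, 5, 10, 15),
                 bw_int = c(0, 0.6, 1.2, 1.8))
  global <- y ~ marsh + week + I(week^2) + marsh:week + marsh:I(week^2)
  bs <- backward_select(global, d, fitter = "gls")
  expect_lte(nrow(bs$removal_log), 5)
  # marsh:week2 carries no signal and is the only removable noise term
  expect_true("marsh:I(week^2)" %in% bs$removal_log$term)
  expect_true(all(c("marsh", "week", "I(week^2)", "marsh:week") %in%
                    bs$retained))
  # main effects are never dropped while their interactions remain
  if (nrow(bs$removal_log) > 0) {
    for (k in seq_len(nrow(bs$removal_log))) {
      dropped <- bs$removal_log$term[k]
      still_in <- c(bs$retained, bs$removal_log$term[-seq_len(k)])
      if (dropped == "week")
        expect_false(any(grepl("week", still_in)))
    }
  }
})

test_that("pure-noise responses collapse toward the intercept", {
  set.seed(105)
  d <- sim_panel(phi = 0)
  bs <- backward_select(y ~ marsh + week + I(week^2), d, fitter = "lm")
  # whatever survives must look significant; removals must have p >= alpha
  expect_true(all(bs$removal_log$p_drop >= 0.05))
  expect_equal(sort(c(bs$retained, bs$removal_log$term)),
               sort(c("marsh", "week", "I(week^2)")))
})

test_that("per-zone models detect an engineered hump and report mains", {
  set.seed(106)
  weeks <- 1:28
  d <- do.call(rbind, lapply(c("A", "B"), function(ms) {
    data.frame(marsh = ms, week = weeks, zone = "mid_marsh_redshank",
               activity_ha = pmax(0.1 + (ms == "B") * 0.3 +
                                    0.4 * weeks - 0.014 * weeks^2 +
                                    rnorm(28, 0, 0.25), 0),
               stringsAsFactors = FALSE)
  }))
  zf <- fit_zone_glm(d, "mid_marsh_redshank", transform = "sqrt")
  expect_equal(zf$term_table$term, c("marsh", "week", "I(week^2)"))
  expect_lt(zf$term_table$p[zf$term_table$term == "I(week^2)"], 0.01)
  expect_lt(coef(zf$final)[["I(week^2)"]], 0)
  # absent zone: NULL with a message
  expect_message(out <- fit_zone_glm(d, "non_redshank"), "absent")
  expect_null(out)
})

test_that("log10_plus_1 transform keeps zero activity finite", {
  set.seed(107)
  d <- data.frame(marsh = "A", week = 1:20, zone = "non_redshank",
                  activity_ha = c(rep(0, 10), runif(10, 0, 2)))
  zf <- fit_zone_glm(d, "non_redshank", transform = "log10_plus_1")
  expect_true(all(is.finite(fitted(zf$final))))
})

test_that("the ACF diagnostic flags AR(1) residuals but not white noise", {
  set.seed(108)
  d <- sim_panel(phi = 0)
  fit <- fit_gls_ar1(y ~ marsh, d, correlation = FALSE)
  diag_wn <- acf_diagnostic(fit)
  expect_lte(mean(diag_wn$flagged), 0.25)
  d2 <- sim_panel(phi = 0.8)
  fit2 <- fit_gls_ar1(y ~ marsh, d2, correlation = FALSE)
  diag_ar <- acf_diagnostic(fit2)
  lag1 <- diag_ar[diag_ar$lag == 1, ]
  expect_gte(sum(lag1$flagged), 2)  # most groups show the lag-1 signal
  # two residuals per group: empty report, no crash
  d3 <- sim_panel(n_weeks = 2)
  fit3 <- fit_gls_ar1(y ~ week, d3, correlation = FALSE)
  expect_equal(nrow(acf_diagnostic(fit3)), 0)
})
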