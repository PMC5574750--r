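# Trampling risk: exposure-period probability algebra, the smooth binomial
# dose-response on cattle activity, and per-cell incubation-length risk maps.

#' Daily trampling probability from a period outcome
#'
#' Back-computes the constant per-day hazard equivalent of an observed
#' period-level trampling probability: `1 - (1 - p_period)^(1/days)`.
#'
#' @param p_period Probability of being trampled at least once during the
#'   period, in [0, 1].
#' @param days Period length in days.
#' @return Daily trampling probability.
#' @export
daily_probability <- function(p_period, days = 14) {
  if (any(!is.finite(p_period)) || any(p_period < 0) || any(p_period > 1))
    stop("p_period must be in [0, 1]")
  if (any(days < 1)) stop("days must be >= 1")
  1 - (1 - p_period)^(1 / days)
}

#' Incubation-length trampling probability from a daily probability
#'
#' `1 - (1 - daily)^incubation_days`: the probability a nest is trampled at
#' least once during a full incubation (24 days for redshank).
#'
#' @param d_daily Daily trampling probability in [0, 1].
#' @param incubation_days Incubation length in days.
#' @return Trampling probability over the incubation period.
#' @export
incubation_probability <- function(d_daily, incubation_days = 24) {
  if (any(!is.finite(d_daily)) || any(d_daily < 0) || any(d_daily > 1))
    stop("d_daily must be in [0, 1]")
  if (any(incubation_days < 1)) stop("incubation_days must be >= 1")
  1 - (1 - d_daily)^incubation_days
}

#' Trampling probabilities for dummy-nest plots
#'
#' Converts per-period broken-disc counts to period, daily, and
#' incubation-length trampling probabilities: `p_k = broken_k / n_discs`,
#' `d_k = 1 - (1 - p_k)^(1/period_days)`, `d_mean = (d_1 + d_2)/2`, and
#' `p24 = 1 - (1 - d_mean)^incubation_days`.
#'
#' @param broken_p1,broken_p2 Discs broken in periods 1 and 2 (broken discs
#'   are replaced after period 1, so both periods have `n_discs` at risk).
#' @param n_discs Discs per plot.
#' @param period_days Exposure-period length in days.
#' @param incubation_days Incubation length in days.
#' @return Data frame `p_period1, p_period2, d1, d2, d_mean, p24`
#'   (vectorized over plots).
#' @export
plot_probabilities <- function(broken_p1, broken_p2, n_discs = 9,
                               period_days = 14, incubation_days = 24) {
  if (any(broken_p1 < 0 | broken_p1 > n_discs) ||
      any(broken_p2 < 0 | broken_p2 > n_discs))
    stop("broken counts must be in [0, n_discs]")
  p1 <- broken_p1 / n_discs
  p2 <- broken_p2 / n_discs
  d1 <- daily_probability(p1, period_days)
  d2 <- daily_probability(p2, period_days)
  d_mean <- (d1 + d2) / 2
  data.frame(p_period1 = p1, p_period2 = p2, d1 = d1, d2 = d2,
             d_mean = d_mean,
             p24 = incubation_probability(d_mean, incubation_days))
}

#' Trampling probabilities for a trial collection
#'
#' @param trials A `trampling_trials` object or its plot-level data frame.
#' @param period_days,incubation_days See [plot_probabilities()].
#' @return Plot-level data frame with the probability columns appended.
#' @export
trial_probabilities <- function(trials, period_days = 14,
                                incubation_days = 24) {
  d <- if (inherits(trials, "trampling_trials")) trials$trials else trials
  cbind(d, plot_probabilities(d$broken_p1, d$broken_p2, d$n_discs[1],
                              period_days, incubation_days))
}

#' Fit the trampling dose-response on cattle activity
#'
#' Binomial generalized additive model of the 24-day trampling outcome on a
#' penalized-spline smooth of local cattle activity. Each plot's two
#' observed periods are converted to the mean daily probability and then to
#' the 24-day scale; the plot then contributes its `n_discs` discs as
#' weighted binomial trials at that probability (`level = "nest"`).
#' `level = "period"` instead models the raw per-period broken counts and
#' converts predictions to the 24-day scale afterwards. The basis dimension
#' is kept small (`k = 4`), consistent with a smoothly saturating curve;
#' smoothness is selected by marginal likelihood.
#'
#' @param trials A `trampling_trials` or plot-level data frame with columns
#'   `activity_ha, broken_p1, broken_p2, n_discs`.
#' @param k Spline basis dimension.
#' @param level `"nest"` (default) or `"period"`; see Details.
#' @param period_days,incubation_days Exposure constants.
#' @return A `dose_response`: list with the `mgcv::gam` fit, `edf`,
#'   `activity_range`, and the modelling level.
#' @export
fit_dose_response <- function(trials, k = 4, level = c("nest", "period"),
                              period_days = 14, incubation_days = 24) {
  level <- match.arg(level)
  d <- if (inherits(trials, "trampling_trials")) trials$trials else trials
  if (nrow(d) < 10) stop("need at least 10 plots to fit the dose-response")
  if (any(d$activity_ha < 0)) stop("negative activity")
  degenerate <- FALSE
  flat_covariate <- length(unique(round(d$activity_ha, 10))) < 3
  if (flat_covariate) {
    # no activity gradient to smooth over: intercept-only binomial fit
    warning("fewer than 3 distinct activity values: ",
            "fitting an intercept-only dose-response")
    pp <- plot_probabilities(d$broken_p1, d$broken_p2, d$n_discs[1],
                             period_days, incubation_days)
    df <- data.frame(y = pp$p24, activity_ha = d$activity_ha, w = d$n_discs)
    fit <- suppressWarnings(
      mgcv::gam(y ~ 1, family = stats::binomial(), weights = w, data = df,
                method = "ML"))
    return(structure(list(fit = fit, level = "nest", edf = 0,
                          chi_sq = NA_real_, s_p_value = NA_real_,
                          dev_expl = 0,
                          activity_range = range(d$activity_ha),
                          period_days = period_days,
                          incubation_days = incubation_days,
                          degenerate = TRUE),
                     class = "dose_response"))
  }
  # the basis cannot exceed the number of distinct covariate values
  k <- min(k, length(unique(round(d$activity_ha, 10))))
  if (level == "nest") {
    pp <- plot_probabilities(d$broken_p1, d$broken_p2, d$n_discs[1],
                             period_days, incubation_days)
    df <- data.frame(y = pp$p24, activity_ha = d$activity_ha,
                     w = d$n_discs)
    if (stats::var(df$y) < 1e-12) degenerate <- TRUE
    fit <- suppressWarnings(
      mgcv::gam(y ~ s(activity_ha, k = k), family = stats::binomial(),
                weights = w, data = df, method = "ML"))
  } else {
    df <- data.frame(
      broken = c(d$broken_p1, d$broken_p2),
      intact = c(d$n_discs - d$broken_p1, d$n_discs - d$broken_p2),
      activity_ha = rep(d$activity_ha, 2))
    if (stats::var(df$broken / (df$broken + df$intact)) < 1e-12)
      degenerate <- TRUE
    fit <- suppressWarnings(
      mgcv::gam(cbind(broken, intact) ~ s(activity_ha, k = k),
                family = stats::binomial(), data = df, method = "ML"))
  }
  if (degenerate)
    warning("all trial outcomes identical: dose-response fit is degenerate")
  s <- summary(fit)
  structure(list(fit = fit, level = level, edf = as.numeric(s$edf[1]),
                 chi_sq = as.numeric(s$chi.sq[1]),
                 s_p_value = as.numeric(s$s.pv[1]),
                 dev_expl = as.numeric(s$dev.expl),
                 activity_range = range(d$activity_ha),
                 period_days = period_days,
                 incubation_days = incubation_days,
                 degenerate = degenerate),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf(
    "dose_response (%s level): edf = %.2f, chi-sq = %.1f, p = %.3g, expl. dev. = %.2f\n",
    x$level, x$edf, x$chi_sq, x$s_p_value, x$dev_expl))
  invisible(x)
}

#' Predict 24-day trampling probability from a dose-response fit
#'
#' Activities beyond the fitted range are clamped to the boundary
#' prediction, with a warning.
#'
#' @param object A `dose_response`.
#' @param activity_ha Cattle activity values (cattle/ha).
#' @param se If `TRUE`, also return 95% confidence bounds (link-scale
#'   normal interval mapped through the inverse link).
#' @param ... Unused.
#' @return Numeric vector of probabilities, or a data frame
#'   `activity_ha, p24, lo, hi` when `se = TRUE`.
#' @export
predict.dose_response <- function(object, activity_ha, se = FALSE, ...) {
  rng <- object$activity_range
  clamped <- activity_ha < rng[1] | activity_ha > rng[2]
  if (any(clamped))
    warning(sum(clamped), " activity value(s) outside the fitted range [",
            signif(rng[1], 3), ", ", signif(rng[2], 3), "] clamped")
  a <- pmin(pmax(activity_ha, rng[1]), rng[2])
  pr <- mgcv::predict.gam(object$fit, newdata = data.frame(activity_ha = a),
                          type = "link", se.fit = TRUE)
  to_p24 <- function(eta) {
    p <- invlogit(eta)
    if (object$level == "period")
      p <- incubation_probability(
        daily_probability(p, object$period_days), object$incubation_days)
    p
  }
  p <- to_p24(as.numeric(pr$fit))
  if (!se) return(p)
  data.frame(activity_ha = activity_ha, p24 = p,
             lo = to_p24(as.numeric(pr$fit - 1.96 * pr$se.fit)),
             hi = to_p24(as.numeric(pr$fit + 1.96 * pr$se.fit)))
}

#' Sampled dose-response curve
#'
#' @param object A `dose_response`.
#' @param from,to,by Activity grid (cattle/ha).
#' @return Data frame `activity_ha, p24, lo, hi` (clamped outside the fitted
#'   range).
#' @export
dose_response_curve <- function(object, from = 0, to = 12, by = 0.05) {
  a <- seq(from, to, by = by)
  suppressWarnings(predict(object, a, se = TRUE))
}

#' Project the dose-response into a per-cell risk map
#'
#' Applies the fitted dose-response to each included cell's cattle activity
#' over the first `incubation_days` of grazing (an `activity_grid` pooled
#' over that window); cells without fixes have activity 0 and take the
#' model's zero-activity prediction.
#'
#' @param model A `dose_response`.
#' @param activity A pooled `activity_grid` over the incubation window (see
#'   [cattle_activity()] with `window`).
#' @return A `risk_map` data frame: `cell_id, x0, y0, cx, cy, zone,
#'   dist_seawall_m, activity_ha, p24` over included cells.
#' @export
predict_risk_map <- function(model, activity) {
  stopifnot(inherits(model, "dose_response"),
            inherits(activity, "activity_grid"))
  if (!activity$pooled)
    stop("risk maps need an activity surface pooled over the incubation window")
  cells <- activity$cells
  inc <- cells[cells$included, , drop = FALSE]
  act <- activity$counts$activity_ha[match(inc$cell_id,
                                           activity$counts$cell_id)]
  act[is.na(act)] <- 0
  p24 <- suppressWarnings(predict(model, act))
  out <- data.frame(cell_id = inc$cell_id, x0 = inc$x0, y0 = inc$y0,
                    cx = inc$cx, cy = inc$cy, zone = inc$zone,
                    dist_seawall_m = inc$dist_seawall_m,
                    activity_ha = act, p24 = p24,
                    stringsAsFactors = FALSE)
  class(out) <- c("risk_map", "data.frame")
  attr(out, "cell_size_m") <- attr(cells, "cell_size_m")
  out
}

#' Mean trampling risk by habitat zone
#'
#' @param risk A `risk_map`.
#' @return Data frame `zone, n_cells, mean_p24, mean_activity_ha`.
#' @export
risk_by_zone <- function(risk) {
  zl <- zone_levels[zone_levels %in% unique(stats::na.omit(risk$zone))]
  do.call(rbind, lapply(zl, function(z) {
    sel <- risk$zone %in% z
    data.frame(zone = z, n_cells = sum(sel),
               mean_p24 = mean(risk$p24[sel]),
               mean_activity_ha = mean(risk$activity_ha[sel]),
               stringsAsFactors = FALSE)
  }))
}

#' Moran's I screen for spatial autocorrelation
#'
#' Moran's I with inverse-distance weights and a permutation p-value,
#' applied to plot-level residuals to check that trial outcomes can be
#' treated as independent. Reported, not auto-corrected.
#'
#' @param values Residuals (e.g. deviance residuals of the dose-response at
#'   plot level).
#' @param x,y Plot coordinates in metres.
#' @param n_perm Number of permutations.
#' @param seed RNG seed for the permutations.
#' @return List `I, expected, p_value, n_perm`.
#' @export
moran_screen <- function(values, x, y, n_perm = 199, seed = 1L) {
  n <- length(values)
  stopifnot(n >= 3, length(x) == n, length(y) == n)
  dm <- as.matrix(stats::dist(cbind(x, y)))
  w <- 1 / dm
  diag(w) <- 0
  w[!is.finite(w)] <- 0
  z <- values - mean(values)
  denom <- sum(z^2)
  s0 <- sum(w)
  stat <- function(zz) (n / s0) * sum(w * outer(zz, zz)) / denom
  I <- stat(z)
  with_seed(seed, {
    perms <- replicate(n_perm, stat(sample(z)))
  })
  p <- (1 + sum(abs(perms) >= abs(I))) / (n_perm + 1)
  list(I = I, expected = -1 / (n - 1), p_value = p, n_perm = n_perm)
}
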