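# Trend models: AR(1) generalized least squares, backward single-term
# elimination respecting marginality, per-zone linear models, and an
# autocorrelation diagnostic.

.transforms <- list(
  identity = function(y) y,
  log10 = function(y) log10(y),
  log10_plus_1 = function(y) log10(y + 1),
  sqrt = function(y) sqrt(y))

.apply_transform <- function(data, formula, transform) {
  resp <- all.vars(formula)[1]
  data[[resp]] <- .transforms[[transform]](data[[resp]])
  data
}

# atoms of a model term for marginality checks: I(week^2) contains week
.term_atoms <- function(label) {
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  atoms <- character(0)
  for (p in parts) {
    m <- regmatches(p, regexec("^I\\(([[:alnum:]._]+)\\^2\\)$", p))[[1]]
    if (length(m) == 2) atoms <- c(atoms, m[2], p) else atoms <- c(atoms, p)
  }
  unique(atoms)
}

# terms whose atoms are not strictly contained in another present term's
.removable_terms <- function(labels) {
  atoms <- lapply(labels, .term_atoms)
  ok <- vapply(seq_along(labels), function(i) {
    !any(vapply(seq_along(labels), function(j) {
      j != i && all(atoms[[i]] %in% atoms[[j]]) &&
        length(atoms[[j]]) > length(atoms[[i]])
    }, logical(1)))
  }, logical(1))
  labels[ok]
}

.gls_ar1_fit <- function(formula, data, group, time, correlation) {
  corr <- if (correlation)
    nlme::corAR1(form = stats::as.formula(paste0("~", time, "|", group)))
  else NULL
  nlme::gls(formula, data = data, correlation = corr, method = "ML",
            na.action = stats::na.omit,
            control = nlme::glsControl(maxIter = 200, msMaxIter = 200,
                                       returnObject = FALSE))
}

.sequential_table <- function(fit, n_obs) {
  at <- as.data.frame(stats::anova(fit))
  p_col <- grep("^p", names(at), ignore.case = TRUE, value = TRUE)[1]
  f_col <- grep("F", names(at), value = TRUE)[1]
  res_df <- n_obs - sum(at$numDF)
  keep <- rownames(at) != "(Intercept)"
  data.frame(term = rownames(at)[keep],
             df = at$numDF[keep],
             res_df = res_df,
             F = at[[f_col]][keep],
             p = at[[p_col]][keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit a generalized least squares trend model with AR(1) errors
#'
#' Maximum-likelihood GLS with, optionally, a first-order autoregressive
#' correlation structure applied within each group (saltmarsh), observations
#' ordered by week: `corAR1(form = ~week|marsh)`. With `correlation =
#' FALSE` the fit reduces to ordinary least squares. The term table reports
#' sequential (type-I) F tests.
#'
#' @param formula Model formula; the response is transformed in place per
#'   `transform`.
#' @param data Data frame, one row per group-week.
#' @param group,time Names of the grouping (marsh) and ordering (week)
#'   columns.
#' @param correlation Include the AR(1) structure?
#' @param transform One of `"identity"`, `"log10"`, `"log10_plus_1"`,
#'   `"sqrt"` applied to the response.
#' @return A `trend_fit`: list with the `nlme::gls` fit, `phi` (AR(1)
#'   coefficient, `NA` without correlation), sequential `term_table`,
#'   `logLik`, and the call ingredients.
#' @export
fit_gls_ar1 <- function(formula, data, group = "marsh", time = "week",
                        correlation = TRUE,
                        transform = c("identity", "log10", "log10_plus_1",
                                      "sqrt")) {
  transform <- match.arg(transform)
  data <- .apply_transform(as.data.frame(data), formula, transform)
  data <- data[order(data[[group]], data[[time]]), , drop = FALSE]
  resp <- all.vars(formula)[1]
  if (stats::var(data[[resp]], na.rm = TRUE) < 1e-12) {
    # constant response: slope inference undefined, return gracefully
    labs <- attr(stats::terms(formula), "term.labels")
    return(structure(list(
      fit = NULL, formula = formula, data = data, group = group, time = time,
      correlation = correlation, transform = transform,
      phi = NA_real_, logLik = NA_real_, degenerate = TRUE,
      coefficients = c(`(Intercept)` = mean(data[[resp]])),
      term_table = data.frame(term = labs, df = NA_real_, res_df = NA_real_,
                              F = NA_real_, p = NA_real_,
                              stringsAsFactors = FALSE)),
      class = "trend_fit"))
  }
  fit <- tryCatch(
    .gls_ar1_fit(formula, data, group, time, correlation),
    error = function(e) stop("GLS fit failed to converge: ",
                             conditionMessage(e)))
  phi <- NA_real_
  if (correlation && !is.null(fit$modelStruct$corStruct))
    phi <- as.numeric(stats::coef(fit$modelStruct$corStruct,
                                  unconstrained = FALSE))
  structure(list(fit = fit, formula = formula, data = data, group = group,
                 time = time, correlation = correlation,
                 transform = transform, phi = phi,
                 logLik = as.numeric(stats::logLik(fit)), degenerate = FALSE,
                 coefficients = stats::coef(fit),
                 term_table = .sequential_table(fit, nrow(data))),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("trend_fit:", deparse(x$formula), "\n")
  cat(sprintf("  transform: %s, AR(1): %s, phi = %s\n", x$transform,
              x$correlation, format(x$phi, digits = 3)))
  print(x$term_table, digits = 3)
  invisible(x)
}

# p-value for dropping `term` from the model with labels `labs`
.drop_p <- function(labs, term, resp, data, fitter, group, time, correlation) {
  red_labs <- setdiff(labs, term)
  full_f <- stats::reformulate(labs, response = resp)
  red_f <- if (length(red_labs))
    stats::reformulate(red_labs, response = resp)
  else stats::as.formula(paste(resp, "~ 1"))
  if (fitter == "lm") {
    full <- stats::lm(full_f, data = data)
    red <- stats::lm(red_f, data = data)
    stats::anova(red, full)[2, "Pr(>F)"]
  } else {
    full <- .gls_ar1_fit(full_f, data, group, time, correlation)
    red <- .gls_ar1_fit(red_f, data, group, time, correlation)
    stat <- 2 * (as.numeric(stats::logLik(full)) -
                   as.numeric(stats::logLik(red)))
    df <- length(stats::coef(full)) - length(stats::coef(red))
    stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE)
  }
}

#' Backward single-term elimination
#'
#' Starting from the global model, repeatedly drops the single least
#' significant removable term with p >= alpha, where a term is removable
#' only if no higher-order term containing it remains (marginality: main
#' effects are kept while their interactions or the quadratic built on them
#' remain). Stops when every removable term has p < alpha. p-values are
#' likelihood-ratio tests between ML fits for GLS models and partial F tests
#' for linear models.
#'
#' @param formula Global model formula.
#' @param data Data frame.
#' @param alpha Retention threshold.
#' @param fitter `"gls"` (ML, optional AR(1)) or `"lm"`.
#' @param scope `"all"` terms, or `"interactions"` only (main effects always
#'   reported, as in per-zone models).
#' @inheritParams fit_gls_ar1
#' @return List of class `backward_fit`: `final` (a [fit_gls_ar1()]
#'   `trend_fit` or an `lm`), `removal_log` (`step, term, p_drop`),
#'   `retained` term labels, `alpha`.
#' @export
backward_select <- function(formula, data, alpha = 0.05,
                            fitter = c("gls", "lm"),
                            scope = c("all", "interactions"),
                            group = "marsh", time = "week",
                            correlation = TRUE,
                            transform = c("identity", "log10",
                                          "log10_plus_1", "sqrt")) {
  fitter <- match.arg(fitter)
  scope <- match.arg(scope)
  transform <- match.arg(transform)
  data <- .apply_transform(as.data.frame(data), formula, transform)
  data <- data[order(data[[group]], data[[time]]), , drop = FALSE]
  resp <- all.vars(formula)[1]
  labs <- attr(stats::terms(formula), "term.labels")
  removal_log <- data.frame(step = integer(0), term = character(0),
                            p_drop = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    cand <- .removable_terms(labs)
    if (scope == "interactions")
      cand <- cand[grepl(":", cand, fixed = TRUE)]
    if (!length(cand)) break
    p <- vapply(cand, function(tm)
      .drop_p(labs, tm, resp, data, fitter, group, time, correlation), 0)
    worst <- which.max(p)
    if (p[worst] < alpha) break
    step <- step + 1L
    removal_log <- rbind(removal_log,
                         data.frame(step = step, term = cand[worst],
                                    p_drop = p[worst],
                                    stringsAsFactors = FALSE))
    labs <- setdiff(labs, cand[worst])
    if (!length(labs)) break
  }
  final_f <- if (length(labs)) stats::reformulate(labs, response = resp)
  else stats::as.formula(paste(resp, "~ 1"))
  final <- if (fitter == "lm") {
    stats::lm(final_f, data = data)
  } else {
    fit_gls_ar1(final_f, data, group = group, time = time,
                correlation = correlation, transform = "identity")
  }
  structure(list(final = final, removal_log = removal_log, retained = labs,
                 alpha = alpha, fitter = fitter, transform = transform),
            class = "backward_fit")
}

#' @export
print.backward_fit <- function(x, ...) {
  cat("backward_fit (", x$fitter, "): retained ",
      if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(intercept only)", "\n", sep = "")
  if (nrow(x$removal_log)) {
    cat("removals:\n")
    print(x$removal_log, digits = 3)
  }
  invisible(x)
}

#' Per-zone linear trend model of cattle activity
#'
#' Gaussian linear model of (transformed) weekly zone activity on saltmarsh
#' identity, week and week squared. Saltmarsh-by-time interactions are
#' included in the global model and backward-eliminated; main effects are
#' always reported.
#'
#' @param zone_data Data frame `marsh, week, zone, activity_ha` (e.g. rows
#'   of [zone_weekly_activity()] across marshes).
#' @param zone Zone label to model.
#' @param transform Response transform (`"sqrt"` or `"log10_plus_1"` deal
#'   with skew; `"identity"` default).
#' @param alpha Elimination threshold for interactions.
#' @return List of class `zone_glm`: `zone`, `final` (`lm`), sequential
#'   `term_table`, `removal_log`; or `NULL` (with a message) when the zone
#'   is absent.
#' @export
fit_zone_glm <- function(zone_data, zone,
                         transform = c("identity", "sqrt", "log10_plus_1",
                                       "log10"),
                         alpha = 0.05) {
  transform <- match.arg(transform)
  d <- zone_data[zone_data$zone == zone, , drop = FALSE]
  if (nrow(d) == 0) {
    message("zone '", zone, "' absent from the data; skipped")
    return(NULL)
  }
  d$marsh <- factor(d$marsh)
  multi <- nlevels(d$marsh) > 1
  labs <- if (multi)
    c("marsh", "week", "I(week^2)", "marsh:week", "marsh:I(week^2)")
  else c("week", "I(week^2)")
  global <- stats::reformulate(labs, response = "activity_ha")
  bs <- backward_select(global, d, alpha = alpha, fitter = "lm",
                        scope = "interactions", group = "marsh",
                        time = "week", transform = transform)
  final <- bs$final
  at <- stats::anova(final)
  term_table <- data.frame(term = rownames(at)[-nrow(at)],
                           df = at$Df[-nrow(at)],
                           res_df = at$Df[nrow(at)],
                           F = at$`F value`[-nrow(at)],
                           p = at$`Pr(>F)`[-nrow(at)],
                           row.names = NULL, stringsAsFactors = FALSE)
  structure(list(zone = zone, final = final, term_table = term_table,
                 removal_log = bs$removal_log, transform = transform),
            class = "zone_glm")
}

#' @export
print.zone_glm <- function(x, ...) {
  cat("zone_glm:", x$zone, "(", x$transform, ")\n")
  print(x$term_table, digits = 3)
  invisible(x)
}

#' Residual autocorrelation diagnostic
#'
#' Per-group residual autocorrelation to `lag_max`, with 95% white-noise
#' bands `+-1.96/sqrt(n)`; lags outside the band are flagged. Used to check
#' that model residuals carry no unmodelled temporal structure.
#'
#' @param object A `trend_fit` (or an `lm` with `data`, `group`, `time`
#'   supplied).
#' @param data,group,time Needed only for plain `lm` objects.
#' @param lag_max Maximum lag.
#' @return Data frame `group, lag, acf, band, flagged` (empty for groups
#'   with fewer than 3 residuals).
#' @export
acf_diagnostic <- function(object, data = NULL, group = "marsh",
                           time = "week", lag_max = 10) {
  if (inherits(object, "trend_fit")) {
    if (object$degenerate %||% FALSE)
      return(data.frame(group = character(0), lag = integer(0),
                        acf = numeric(0), band = numeric(0),
                        flagged = logical(0)))
    data <- object$data
    group <- object$group
    time <- object$time
    res <- if (object$correlation)
      stats::residuals(object$fit, type = "normalized")
    else stats::residuals(object$fit)
  } else {
    if (is.null(data)) stop("data required for non-trend_fit objects")
    res <- stats::residuals(object)
  }
  out <- list()
  for (g in unique(data[[group]])) {
    sel <- data[[group]] == g
    r <- res[sel][order(data[[time]][sel])]
    n <- length(r)
    if (n < 3) next
    lm_g <- min(lag_max, n - 1)
    a <- as.numeric(stats::acf(r, lag.max = lm_g, plot = FALSE)$acf)[-1]
    band <- 1.96 / sqrt(n)
    out[[length(out) + 1L]] <-
      data.frame(group = g, lag = seq_along(a), acf = a, band = band,
                 flagged = abs(a) > band, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(group = character(0), lag = integer(0),
                      acf = numeric(0), band = numeric(0),
                      flagged = logical(0)))
  do.call(rbind, out)
}
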