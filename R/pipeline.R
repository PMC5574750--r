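# End-to-end pipeline: configuration, simulation bundle, analysis bundle.

#' Default run configuration
#'
#' All defaults are the analysis constants: 50 m grid cells with the
#' 6.25 m2 inclusion rule, week 1 starting 14 April, 28-week season,
#' 14-day trial periods, 24-day incubation, alpha = 0.05, livestock-unit
#' coefficient 0.8 for young cattle.
#'
#' @param seed Integer seed for all stochastic stages.
#' @return Nested configuration list (YAML-serializable).
#' @export
default_config <- function(seed = 1L) {
  sc <- sim_config()
  sim <- sc[setdiff(names(sc), c("rng_seed", "attraction_point"))]
  sim$week1_start_date <- as.character(sim$week1_start_date)
  sim$grazing_start_date <- as.character(sim$grazing_start_date)
  sim$grazing_end_date <- as.character(sim$grazing_end_date)
  sim$zone_band_widths_m <- as.list(sim$zone_band_widths_m)
  sim$true_dose_response <- as.list(sim$true_dose_response)
  list(
    paths = list(out_dir = "saltgraze_run",
                 marsh_geojson = "marsh.geojson",
                 fixes_csv = "fixes.csv",
                 plots_csv = "plots.csv",
                 trials_csv = "trials.csv"),
    calendar = list(week1_start = as.character(sc$week1_start_date),
                    n_weeks = sc$season_weeks, nesting_end_week = 12L),
    grid = list(cell_size_m = 50, inclusion_threshold_m2 = 6.25),
    model = list(alpha = 0.05, lsu_coefficient = 0.8,
                 incubation_days = 24L, period_days = 14L, gam_k = 4L,
                 ca100_transform = "log10", p95_transform = "identity",
                 zone_transform = "sqrt"),
    sim = sim,
    seed = as.integer(seed))
}

#' Read / write run configurations as YAML
#'
#' @param path YAML file.
#' @return `read_config`: the configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  utils::modifyList(base, cfg)
}

#' @rdname read_config
#' @param config Configuration list.
#' @return `write_config`: `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_hash <- function(config) fnv1a_hash(yaml::as.yaml(config))

.sim_config_from <- function(config) {
  sim <- config$sim
  sim$zone_band_widths_m <- unlist(sim$zone_band_widths_m)
  sim$true_dose_response <- unlist(sim$true_dose_response)
  sim$rng_seed <- as.integer(config$seed)
  do.call(sim_config, sim)
}

#' Simulate a synthetic study bundle to disk
#'
#' Generates the marsh geometry, herd tracks and dummy-nest trials under the
#' configured conditions and writes them in the interchange formats the
#' analysis reads back: marsh GeoJSON, fix CSV, plot-layout CSV, disc-level
#' trial CSV and a YAML configuration echo. Deterministic under
#' `config$seed`.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the written paths and the in-memory
#'   objects.
#' @export
run_simulate <- function(config = default_config(),
                         out_dir = config$paths$out_dir) {
  scfg <- .sim_config_from(config)   # validates before any write
  seed <- as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  marsh <- generate_marsh(scfg, seed = seed)
  tracks <- simulate_herd_tracks(marsh, scfg, seed = seed + 1L)
  grid <- build_grid(marsh, config$grid$cell_size_m,
                     inclusion_threshold_m2 = config$grid$inclusion_threshold_m2)
  grid <- assign_zones(grid, marsh)
  t0 <- as.POSIXct(paste(scfg$grazing_start_date, "00:00:00"), tz = "UTC")
  act24 <- cattle_activity(tracks, grid,
                           window = c(t0, t0 + config$model$incubation_days *
                                        86400))
  plots <- sample_plot_layout(marsh, seed = seed + 2L)
  truth <- true_dose_response(scfg$true_dose_response[["beta0"]],
                              scfg$true_dose_response[["beta1"]],
                              horizon_days = config$model$period_days)
  trials <- simulate_trampling_trials(act24, plots, truth, seed = seed + 3L)

  write_marsh_geojson(marsh, p(config$paths$marsh_geojson))
  write_fixes_csv(tracks, p(config$paths$fixes_csv))
  utils::write.csv(plots, p(config$paths$plots_csv), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(trials$discs, p(config$paths$trials_csv),
                   row.names = FALSE, quote = FALSE)
  echo <- config
  echo$provenance <- list(seed = seed, config_hash = config_hash(config))
  write_config(echo, p("config.yaml"))
  invisible(list(out_dir = out_dir,
                 paths = lapply(config$paths[-1], function(f) p(f)),
                 marsh = marsh, tracks = tracks, grid = grid,
                 activity_24d = act24, plots = plots, trials = trials))
}

#' Rebuild plot-level trials from disc records and plot positions
#'
#' @param discs Disc-level table `plot_id, disc_id, period, broken`.
#' @param plots Plot layout `plot_id, x_m, y_m`.
#' @param activity Pooled `activity_grid` over the exposure window, used to
#'   attach each plot's local cattle activity (cell containing the plot
#'   centre).
#' @return A `trampling_trials` object.
#' @export
trials_from_discs <- function(discs, plots, activity) {
  n_discs <- max(stats::aggregate(broken ~ plot_id + period, data = discs,
                                  FUN = length)$broken)
  agg <- stats::aggregate(broken ~ plot_id + period, data = discs, FUN = sum)
  b1 <- agg[agg$period == 1, ]
  b2 <- agg[agg$period == 2, ]
  loc <- locate_cells(activity$cells, plots$x_m, plots$y_m)
  ok <- !is.na(loc$cell_id) & loc$included
  if (any(!ok))
    warning(sum(!ok), " plot(s) outside included cells excluded: ",
            paste(plots$plot_id[!ok], collapse = ", "))
  plots <- plots[ok, , drop = FALSE]
  loc <- loc[ok, , drop = FALSE]
  act <- activity$counts$activity_ha[match(loc$cell_id,
                                           activity$counts$cell_id)]
  act[is.na(act)] <- 0
  trials <- data.frame(
    plot_id = plots$plot_id, x_m = plots$x_m, y_m = plots$y_m,
    cell_id = loc$cell_id, activity_ha = act, n_discs = n_discs,
    broken_p1 = b1$broken[match(plots$plot_id, b1$plot_id)],
    broken_p2 = b2$broken[match(plots$plot_id, b2$plot_id)],
    stringsAsFactors = FALSE)
  structure(list(trials = trials, discs = discs, seed = NA_integer_),
            class = "trampling_trials")
}

#' Run the full analysis on an input bundle
#'
#' Reads the marsh geometry, fixes and (if present) trial records from
#' `in_dir`, then runs the staged analysis: gridding and zone assignment,
#' weekly activity surfaces, range metrics (CA100, 95th-percentile distance
#' to the sea wall), AR(1) GLS trend models with backward elimination,
#' per-zone linear models, trampling probability conversion, the binomial
#' dose-response, and the 24-day risk map. Results are written to
#' `out_dir`; every table carries the seed and configuration hash. When the
#' trial files are missing, the trampling stage is skipped with a logged
#' notice.
#'
#' @param config Configuration list.
#' @param in_dir Directory holding the input bundle (default: the simulate
#'   output directory).
#' @param out_dir Results directory.
#' @return Invisibly, a list of class `saltgraze_run` with all stage
#'   results.
#' @export
run_analysis <- function(config = default_config(),
                         in_dir = config$paths$out_dir,
                         out_dir = file.path(in_dir, "results")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p_in <- function(f) file.path(in_dir, f)
  p_out <- function(f) file.path(out_dir, f)
  hash <- config_hash(config)
  hdr <- list(config_hash = hash, seed = config$seed)
  log_lines <- c(sprintf("saltgraze run: seed %d, config %s",
                         config$seed, hash))
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  marsh <- stage("read_marsh",
                 read_marsh_geojson(p_in(config$paths$marsh_geojson)))
  scfg <- .sim_config_from(config)
  tracks <- stage("read_fixes", read_fixes(
    p_in(config$paths$fixes_csv), herd_size = config$sim$herd_size,
    marsh_id = marsh$marsh_id,
    grazing_start = config$sim$grazing_start_date,
    grazing_end = config$sim$grazing_end_date))
  say("fixes read: %d (%d duplicates dropped)", nrow(tracks$fixes),
      attr(tracks, "n_duplicates") %||% 0)
  cal <- season_calendar(config$calendar$week1_start, config$calendar$n_weeks,
                         config$calendar$nesting_end_week)
  tracks <- stage("assign_weeks", assign_weeks(tracks, cal))

  grid <- stage("build_grid", build_grid(
    marsh, config$grid$cell_size_m,
    inclusion_threshold_m2 = config$grid$inclusion_threshold_m2))
  grid <- stage("assign_zones", assign_zones(grid, marsh))
  say("grid: %d cells, %d included", nrow(grid), sum(grid$included))

  act <- stage("cattle_activity", cattle_activity(tracks, grid))
  say("weekly activity: %d weeks, %d excluded fixes",
      nrow(act$week_totals), sum(act$week_totals$n_excluded))
  wm <- stage("weekly_metrics", weekly_metrics(tracks, act, marsh$seawall))
  write_activity_csv(act, p_out("activity_weekly.csv"), hdr)
  .write_table(wm, p_out("weekly_metrics.csv"), hdr)

  stock <- seasonal_cattle_density(config$sim$herd_size,
                                   config$sim$marsh_area_ha,
                                   config$model$lsu_coefficient)
  say("stocking: SCD %.2f, LSU %.2f", stock$scd_per_ha, stock$lsu_per_ha)

  trend_data <- wm
  trend_data$week2 <- NULL
  single <- length(unique(trend_data$marsh)) == 1
  labs <- if (single) c("week", "I(week^2)")
  else c("marsh", "week", "I(week^2)", "marsh:week", "marsh:I(week^2)")
  gf <- function(resp) stats::reformulate(labs, response = resp)
  ca_bs <- stage("trend_ca100", backward_select(
    gf("ca100_pct"), trend_data, alpha = config$model$alpha, fitter = "gls",
    transform = config$model$ca100_transform))
  p95_bs <- stage("trend_p95", backward_select(
    gf("p95_dist_m"), trend_data, alpha = config$model$alpha, fitter = "gls",
    transform = config$model$p95_transform))
  .write_table(ca_bs$removal_log, p_out("trend_ca100_removals.csv"), hdr)
  .write_table(p95_bs$removal_log, p_out("trend_p95_removals.csv"), hdr)
  if (inherits(ca_bs$final, "trend_fit"))
    .write_table(ca_bs$final$term_table, p_out("trend_ca100_terms.csv"), hdr)
  if (inherits(p95_bs$final, "trend_fit"))
    .write_table(p95_bs$final$term_table, p_out("trend_p95_terms.csv"), hdr)

  zwa <- zone_weekly_activity(act)
  zwa$marsh <- tracks$marsh_id
  zone_fits <- list()
  for (z in unique(zwa$zone)) {
    zf <- stage(paste0("zone_glm_", z),
                fit_zone_glm(zwa, z, transform = config$model$zone_transform,
                             alpha = config$model$alpha))
    if (!is.null(zf)) zone_fits[[z]] <- zf
  }
  zone_tables <- do.call(rbind, lapply(zone_fits, function(zf)
    cbind(zone = zf$zone, zf$term_table)))
  if (!is.null(zone_tables))
    .write_table(zone_tables, p_out("zone_glm_terms.csv"), hdr)

  nv <- never_visited_fraction(act)
  say("never-visited: %.1f%% of included cells", nv)

  trials <- NULL; dr <- NULL; risk <- NULL; moran <- NULL; act24 <- NULL
  trials_path <- p_in(config$paths$trials_csv)
  plots_path <- p_in(config$paths$plots_csv)
  if (file.exists(trials_path) && file.exists(plots_path)) {
    t0 <- as.POSIXct(paste(scfg$grazing_start_date, "00:00:00"), tz = "UTC")
    act24 <- stage("activity_24d", cattle_activity(
      tracks, grid, window = c(t0, t0 + config$model$incubation_days * 86400)))
    discs <- utils::read.csv(trials_path, stringsAsFactors = FALSE)
    plots <- utils::read.csv(plots_path, stringsAsFactors = FALSE)
    trials <- stage("trials", trials_from_discs(discs, plots, act24))
    tp <- trial_probabilities(trials, config$model$period_days,
                              config$model$incubation_days)
    .write_table(tp, p_out("trampling_probabilities.csv"), hdr)
    dr <- stage("dose_response", fit_dose_response(
      trials, k = config$model$gam_k,
      period_days = config$model$period_days,
      incubation_days = config$model$incubation_days))
    .write_table(dose_response_curve(dr), p_out("dose_response_curve.csv"),
                 hdr)
    moran <- stage("moran_screen", moran_screen(
      stats::residuals(dr$fit, type = "deviance"),
      trials$trials$x_m, trials$trials$y_m, seed = config$seed))
    say("dose-response: edf %.2f, chi-sq %.1f; Moran's I %.3f (p = %.3f)",
        dr$edf, dr$chi_sq, moran$I, moran$p_value)
    risk <- stage("risk_map", predict_risk_map(dr, act24))
    .write_table(as.data.frame(risk), p_out("risk_map.csv"), hdr)
    write_cells_geojson(risk, p_out("risk_map.geojson"), header = hdr)
    .write_table(risk_by_zone(risk), p_out("risk_by_zone.csv"), hdr)
  } else {
    say("trampling stage skipped: %s not found",
        if (!file.exists(trials_path)) trials_path else plots_path)
  }

  writeLines(log_lines, p_out("run_log.txt"))
  invisible(structure(
    list(marsh = marsh, tracks = tracks, grid = grid, activity = act,
         weekly_metrics = wm, stocking = stock, trend_ca100 = ca_bs,
         trend_p95 = p95_bs, zone_fits = zone_fits,
         never_visited_pct = nv, activity_24d = act24, trials = trials,
         dose_response = dr, moran = moran, risk_map = risk,
         out_dir = out_dir, log = log_lines),
    class = "saltgraze_run"))
}

.write_table <- function(d, path, header = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header))
    writeLines(sprintf("# %s: %s", k, header[[k]]), con)
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
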