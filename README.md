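# saltgraze

Quantifying the spatio-temporal overlap between grazing cattle and
ground-nesting shorebirds on saltmarshes — and what it means for nest
trampling.

## The problem

Breeding redshank (*Tringa totanus*) on European saltmarshes nest in the
grassy higher-elevation zones close to the landward sea wall, between
mid-April and mid-July. Conservation grazing keeps that habitat suitable,
and stocking guidance is expressed as a marsh-wide seasonal cattle density
(SCD, cattle per hectare). But free-roaming cattle do not spread evenly:
GPS-collared herds concentrate near the sea wall — exactly where and when
redshank nest — so the trampling hazard a nest experiences can be far
higher than the marsh-wide density suggests.

`saltgraze` is an R package for movement ecologists and conservation
practitioners that implements this analysis end to end:

- **Telemetry**: read and validate GPS fix tables (CSV/GPX), collar spans,
  cattle days, half-open weekly bins anchored at 14 April.
- **Gridding**: a 50 × 50 m analysis grid with the strict >6.25 m²
  saltmarsh inclusion rule, habitat-zone assignment by largest area, and
  the cattle-activity statistic per cell and window
  `A = H · (n/N) / area_ha` (mean cattle per hectare of the cell).
- **Range metrics**: CA100 (the % of included cells holding all of a
  week's activity), never-visited fraction, per-zone activity shares, and
  the 95th-percentile distance to the sea wall.
- **Trend models**: maximum-likelihood GLS with `corAR1(~week|marsh)`
  errors, backward single-term elimination respecting marginality,
  per-zone linear models, and residual ACF diagnostics (via `nlme`).
- **Trampling risk**: dummy-nest period outcomes converted to daily and
  24-day (incubation-length) probabilities,
  `d = 1 − (1 − p_period)^(1/14)` and `p24 = 1 − (1 − d̄)^24`, a binomial
  penalized-spline dose-response of `p24` on local cattle activity (via
  `mgcv`), and per-cell 24-day risk maps with zone summaries.
- **Synthetic data**: a seeded simulator (marsh geometry, biased
  correlated random-walk herd tracks with a hump-shaped seasonal range,
  Bernoulli disc trials) so the full pipeline runs and is tested with no
  field data.

## A worked example

```r
library(saltgraze)

cfg    <- sim_config(rng_seed = 1)          # 126 ha, 39 cattle, 4 collars
marsh  <- generate_marsh(cfg)
tracks <- assign_weeks(simulate_herd_tracks(marsh, cfg), season_calendar())
grid   <- assign_zones(build_grid(marsh), marsh)

activity <- cattle_activity(tracks, grid)
weekly   <- weekly_metrics(tracks, activity, marsh$seawall)
weekly[weekly$week %in% c(6, 12, 19, 28), ]
#>  marsh week n_fixes ca100_pct p95_dist_m
#>    SYN    6    2016  8.134921   149.8951
#>    SYN   12    2016 17.063492   223.7142
#>    SYN   19    2016 32.738095   345.3745
#>    SYN   28    2016 12.301587   191.2608
```

The herd starts tightly packed near the sea wall (week 6: 8% of the marsh
used, 95% of fixes within 150 m), spreads to a mid-season peak (week 19:
33%, 345 m) and contracts again — while more than half the marsh is never
grazed at all:

```r
never_visited_fraction(activity)
#> [1] 56.34921
seasonal_cattle_density(cfg$herd_size, cfg$marsh_area_ha)
#> SCD 0.31 ha^-1, LSU 0.25 ha^-1 (coefficient 0.80)
```

Trampling risk, from dummy-nest trials to a 24-day risk map:

```r
t0     <- as.POSIXct(paste(cfg$grazing_start_date, "00:00"), tz = "UTC")
act24  <- cattle_activity(tracks, grid, window = c(t0, t0 + 24 * 86400))
plots  <- sample_plot_layout(marsh, seed = 2)
trials <- simulate_trampling_trials(act24, plots, true_dose_response(),
                                    seed = 3)
dose   <- fit_dose_response(trials)
risk   <- predict_risk_map(dose, act24)
risk_by_zone(risk)
#>                zone n_cells mean_p24 mean_activity_ha
#>       non_saltmarsh      36   0.1879            1.970
#>  mid_marsh_redshank     180   0.0822            0.473
#>  elytrigia_redshank      72   0.0264            0.000
#>        non_redshank      216  0.0264            0.000
```

Even at a marsh-wide density of 0.31 cattle/ha, the mean probability that
a nest is trampled during one incubation is ~3× higher in the mid-marsh
redshank nesting zone than in the seaward non-redshank zone, because
that is where the herd spends the nesting season.

The same analysis runs end to end from files (GeoJSON marsh, CSV fixes and
trials) via `run_simulate()` / `run_analysis()` or the thin CLI wrapper in
`inst/scripts/trample-risk`.

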