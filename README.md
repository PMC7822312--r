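# tripfidelity

Quantifying individual foraging consistency in central-place foragers from
GPS tracking data.

Breeding seabirds such as Adélie penguins (*Pygoscelis adeliae*) commute
between their nest and sea-ice foraging grounds over repeated trips. Two
questions recur in movement ecology: how *repeatable* is an individual's
foraging behaviour (does the same bird keep doing the same thing?), and how
*site-faithful* is it (does it return to the same place?), and how both
depend on the environment — here, sea-ice concentration around the colony.
`tripfidelity` implements that full analysis as a tested, reusable pipeline:

- **Track QC** (`read_tracks`, `clean_fixes`, `split_trips`,
  `complete_or_discard`, `resample_trip`): duplicate removal, a 10 km/h
  speed filter, trip splitting at a colony radius, virtual completion of
  truncated recordings from nest-check return times (retained only when
  > 70% of the trip duration was recorded), and 20-minute resampling.
- **Trip effort metrics** (`compute_metrics`): total duration (h), total
  and maximal distance (km, great-circle), bearing to the most distal
  point, and the days-since-peak-hatching timing covariate.
- **Phase segmentation** (`normalize_trips`, `fit_three_segment`,
  `extract_central_phase`): trips pooled on the normalized profile of
  % maximal distance vs % elapsed duration trace a bell; a continuous
  two-changepoint piecewise-linear model (exhaustive least-squares grid
  search) finds the fractions *f₁ < f₂* that cut each trip into outbound,
  central (foraging) and inbound phases.
- **Sea ice** (`ice_field`, `sample_at`, `regrid_to_fine`,
  `mean_sic_region`, `annual_prospected_area`, `trip_pair_ice`): daily
  gridded % concentration at 6.25 / 12.5 km, per-fix extraction, regional
  means over trip windows at two spatial scales (a fixed study rectangle,
  64–67° S / 137–143° E, and the annual convex hull of all trips).
- **Repeatability** (`fit_lmm`, `select_fixed_effects`, `bootstrap_R`,
  `adjusted_vs_nonadjusted`): Gaussian random-intercept mixed models per
  trait with backward AIC selection of year × season-timing fixed effects;

  R = σ²_A / (σ²_A + σ²),

  the fraction of trait variance between individuals (low < 0.25 ≤
  moderate ≤ 0.5 < high), with parametric-bootstrap SE and percentile CI.
- **Site fidelity** (`nnd`, `fidelity_table`): the nearest-neighbour
  distance — for each fix of trip *n+1*'s central phase, the distance to
  the nearest fix of trip *n*'s central phase, averaged over focal fixes.
  Low NND = high fidelity.
- **Inference** (`fit_year_model`, `fit_year_timing_model`,
  `fit_smooth_ice_model`): year effects on log NND, Tukey-adjusted
  pairwise year contrasts at the mean season timing (emmeans), and
  penalized-spline smooths of log NND on sea-ice covariates with a bird
  random intercept (mgcv, REML).
- **Synthetic study generator** (`simulate_cohort`, `simulate_icefields`,
  `simulate_trait_data`): seeded three-phase correlated-walk trips with
  known trait variance components, phase fractions, patch fidelity modes,
  truncated recordings, nest checks, and daily receding ice fields — the
  ground truth every estimator is tested against.
- **Pipeline** (`run_pipeline`): configuration-driven orchestration of all
  stages with CSV artifacts, a run log and a summary report; a thin CLI
  wrapper lives at `inst/scripts/tripfidelity_pipeline.R`.

## Worked example

```r
library(tripfidelity)

cfg  <- sim_config(n_birds = 25, trips_per_bird = 3, seed = 42)
sim  <- simulate_cohort(cfg)
trips <- qc_deployments(cohort_deployments(sim), sim$nest_checks)
summarize_cohort(trips)
#> Cohort summary
#>   season n_ind n_trip mean_trips  sd_trips
#>  2015-16    25     72       2.88 0.4396969
#> Total: 25 individuals, 72 trips (2.88 +/- 0.44 trips/bird)

fit_three_segment(normalize_trips(trips), grid_step = 0.5)
#> <phase model: breakpoints 30.0% and 70.0% of trip duration>

mt <- trip_metrics_table(trips, sim$peak_hatch)
f  <- select_fixed_effects(lmm_spec("total_duration", transform = "log"), mt)
bootstrap_R(f, n_boot = 200, seed = 1)
#> <repeatability R = 0.509 +/- 0.115 (high, non-adjusted)>

fid <- fidelity_table(trips, phase_model(30, 70), sim$peak_hatch)
sprintf("%d trip pairs, mean NND %.1f km", nrow(fid), mean(fid$nnd))
#> [1] "47 trip pairs, mean NND 25.7 km"
```

At this seed four loggers die at sea; their truncated recordings clear the
70% completion rule and are completed with a virtual colony fix at the
nest-check return time, while the three trips those birds would have made
afterwards are never recorded (75 planned, 72 analysed). The generator's true phase fractions are 30%
and 70%; the pooled changepoint fit recovers both exactly at the 0.5% grid
from the noisy walks. The trait generator draws log trip durations with a
true repeatability of 0.42; the mixed-model estimate on this small cohort
is 0.51 ± 0.12, truth well inside its interval. The mean NND of 25.7 km
reflects the default "faithful" mode, where each bird's trips revisit its
own foraging patch; explorer cohorts give distinctly larger values.

Whole-pipeline equivalent, writing all stage CSVs, a log and a report:

```r
run_pipeline(list(n_birds = 25, phase_mode = "fit"), out = "out", seed = 42)
```

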