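test_that("the generator is exactly reproducible from its seed", {
  cfg <- sim_config(n_birds = 5, trips_per_bird = 2, seed = 99)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$nest_checks, s2$nest_checks)
  expect_identical(s1$truth$trips, s2$truth$trips)
  f1 <- simulate_icefields(cfg, as.Date("2016-01-05") + 0:2)
  f2 <- simulate_icefields(cfg, as.Date("2016-01-05") + 0:2)
  expect_identical(f1[[1]]$grid, f2[[1]]$grid)
  # and sensitive to the seed
  s3 <- simulate_cohort(sim_config(n_birds = 5, trips_per_bird = 2, seed = 100))
  expect_false(identical(s1$tracks, s3$tracks))
})

test_that("cohort truth matches the requested structure", {
  cfg <- sim_config(n_birds = 6, trips_per_bird = 3,
                    seasons = c("2014-15", "2015-16"),
                    truncation_prob = 0, seed = 41)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$truth$trips), 18)
  expect_setequal(unique(sim$truth$trips$season), c("2014-15", "2015-16"))
  expect_equal(sort(names(sim$peak_hatch)), c("2014-15", "2015-16"))
  # true breakpoint times sit at the configured fractions
  tt <- sim$truth$trips
  frac1 <- as.numeric(difftime(tt$t_f1, tt$departure, units = "hours")) /
    tt$true_duration_h
  expect_equal(frac1, rep(0.30, 18), tolerance = 1e-9)
  # trait truth: R implied by the variance components
  expect_equal(sim$truth$true_R$log_max_distance,
               0.30^2 / (0.30^2 + 0.35^2))
  # explorer cohorts have zero true repeatability
  exp_sim <- simulate_cohort(sim_config(n_birds = 4, trips_per_bird = 2,
                                        fidelity_mode = "explorer", seed = 42))
  expect_equal(exp_sim$truth$true_R$heading, 0)
})

test_that("degenerate variance configs propagate to the estimator", {
  # no within-individual variance: repeatability of the trait near 1
  cfg <- sim_config(n_birds = 20, trips_per_bird = 4,
                    logdist_within_sd = 0.001, truncation_prob = 0,
                    spike_prob = 0, dup_prob = 0, seed = 43)
  sim <- simulate_cohort(cfg)
  trips <- suppressMessages(qc_deployments(cohort_deployments(sim),
                                           sim$nest_checks))
  mt <- trip_metrics_table(trips, sim$peak_hatch)
  f <- fit_lmm(lmm_spec("max_distance", fixed = character(),
                        transform = "log"), mt)
  expect_gt(repeatability(f)$R, 0.9)
  # no between-individual variance: repeatability near 0
  cfg0 <- sim_config(n_birds = 30, trips_per_bird = 4,
                     logdist_between_sd = 0, truncation_prob = 0,
                     spike_prob = 0, dup_prob = 0, seed = 44)
  sim0 <- simulate_cohort(cfg0)
  trips0 <- suppressMessages(qc_deployments(cohort_deployments(sim0),
                                            sim0$nest_checks))
  mt0 <- trip_metrics_table(trips0, sim0$peak_hatch)
  f0 <- fit_lmm(lmm_spec("max_distance", fixed = character(),
                         transform = "log"), mt0)
  expect_lt(repeatability(f0)$R, 0.1)
})

test_that("trip walks realize the configured geometry", {
  cfg <- sim_config(n_birds = 10, trips_per_bird = 2, truncation_prob = 0,
                    spike_prob = 0, dup_prob = 0, seed = 45)
  sim <- simulate_cohort(cfg)
  trips <- suppressMessages(qc_deployments(cohort_deployments(sim),
                                           sim$nest_checks))
  mt <- trip_metrics_table(trips, sim$peak_hatch)
  tt <- sim$truth$trips
  key <- paste(mt$bird_id, mt$trip_index)
  tkey <- paste(tt$bird_id, tt$trip_index)
  ratio <- mt$max_distance / tt$true_max_km[match(key, tkey)]
  # realized maximal distance tracks the drawn patch distance
  expect_lt(median(abs(ratio - 1)), 0.15)
  # infeasible geometry is rejected
  expect_error(simulate_cohort(sim_config(n_birds = 2, trips_per_bird = 1,
                                          logdist_mean = log(500), seed = 1)),
               "infeasible")
})

test_that("truncation exercises the completion rule", {
  cfg <- sim_config(n_birds = 20, trips_per_bird = 2, truncation_prob = 1,
                    truncation_fraction = 0.8, seed = 46)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$truth$trips$truncated))
  trips <- suppressMessages(qc_deployments(cohort_deployments(sim),
                                           sim$nest_checks))
  expect_gt(length(trips), 0)
  expect_true(all(vapply(trips, `[[`, TRUE, "completed_virtually")))
  # recordings cut at half the trip are discarded wholesale
  cfg50 <- sim_config(n_birds = 5, trips_per_bird = 2, truncation_prob = 1,
                      truncation_fraction = 0.5, seed = 47)
  sim50 <- simulate_cohort(cfg50)
  trips50 <- suppressMessages(qc_deployments(cohort_deployments(sim50),
                                             sim50$nest_checks))
  expect_length(trips50, 0)
})

test_that("ice fields recede as configured", {
  cfg <- sim_config(ice_noise_sd = 0, ice_recession_per_day = 0.02, seed = 48)
  dates <- as.Date("2016-01-01") + 0:10
  flds <- simulate_icefields(cfg, dates)
  m <- vapply(flds, function(f) mean(f$grid, na.rm = TRUE), 0)
  # noise-free: non-increasing, with the closed-form 10-day decline
  expect_true(all(diff(m) <= 1e-9))
  expect_equal(m[[11]] / m[[1]], 0.98^10, tolerance = 1e-6)
  # zero recession and zero noise: constant fields
  cfg0 <- sim_config(ice_noise_sd = 0, ice_recession_per_day = 0, seed = 48)
  flds0 <- simulate_icefields(cfg0, dates[1:3])
  expect_identical(flds0[[1]]$grid, flds0[[3]]$grid)
  # concentrations bounded and land masked near the colony
  expect_true(all(is.na(flds[[1]]$grid) |
                    (flds[[1]]$grid >= 0 & flds[[1]]$grid <= 100)))
  expect_true(any(is.na(flds[[1]]$grid)))
})

test_that("written cohorts are read back equivalently", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(sim_config(n_birds = 3, trips_per_bird = 2, seed = 49))
  write_cohort(sim, dir)
  deps_file <- read_tracks(file.path(dir, "tracks.csv"))
  deps_mem <- cohort_deployments(sim)
  expect_equal(length(deps_file), length(deps_mem))
  expect_equal(deps_file[[1]]$fixes$lon, deps_mem[[1]]$fixes$lon)
  expect_equal(deps_file[[1]]$fixes$timestamp, deps_mem[[1]]$fixes$timestamp)
  nc <- read_nest_checks(file.path(dir, "nest_checks.csv"))
  expect_equal(nrow(nc), nrow(sim$nest_checks))
})
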