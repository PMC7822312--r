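fake_fit <- function(sigma2_A, sigma2, fixed = character()) {
  structure(list(sigma2_A = sigma2_A, sigma2 = sigma2,
                 spec = list(fixed = fixed)), class = "lmm_fit")
}

test_that("R formula and categories follow the variance-ratio definition", {
  r0 <- repeatability(fake_fit(0, 1))
  expect_equal(r0$R, 0); expect_equal(r0$category, "low")
  r5 <- repeatability(fake_fit(1, 1))
  expect_equal(r5$R, 0.5); expect_equal(r5$category, "moderate")
  r75 <- repeatability(fake_fit(3, 1))
  expect_equal(r75$R, 0.75); expect_equal(r75$category, "high")
  expect_error(repeatability(fake_fit(0, 0)), "degenerate")
  expect_false(repeatability(fake_fit(1, 1))$adjusted)
  expect_true(repeatability(fake_fit(1, 1, "year"))$adjusted)
})

test_that("variance components are recovered from known simulations", {
  # identical birds: the between-individual component is negligible relative
  # to the residual variance (the REML estimate sits on the zero boundary,
  # with small positive excursions at finite n)
  for (s in 1:3) {
    d0 <- simulate_trait_data(200, 5, between_sd = 0, within_sd = 1, seed = s)
    f0 <- fit_lmm(lmm_spec("y", fixed = character(), transform = "identity"),
                  d0)
    expect_lt(f0$sigma2_A / (f0$sigma2_A + f0$sigma2), 0.05)
  }
  # sigma2_A = sigma2 = 1 at 100 x 5: both within 15%
  d1 <- simulate_trait_data(100, 5, 1, 1, mu = 2, seed = 6)
  f1 <- fit_lmm(lmm_spec("y", fixed = character(), transform = "identity"), d1)
  expect_lt(abs(f1$sigma2_A - 1), 0.15)
  expect_lt(abs(f1$sigma2 - 1), 0.15)
  # closed-form balanced one-way ANOVA oracle for the same components
  ms <- anova(lm(y ~ bird_id, data = d1))
  mse <- ms$`Mean Sq`[2]
  msa <- ms$`Mean Sq`[1]
  expect_equal(f1$sigma2, mse, tolerance = 0.02)
  expect_equal(f1$sigma2_A, (msa - mse) / 5, tolerance = 0.02)
  # a single individual is rejected
  d_one <- d1[d1$bird_id == d1$bird_id[1], ]
  expect_error(fit_lmm(lmm_spec("y", fixed = character(),
                                transform = "identity"), d_one),
               "individuals")
})

test_that("R is invariant to rescaling the response", {
  d <- simulate_trait_data(50, 4, 0.8, 1, mu = 3, seed = 8)
  f <- fit_lmm(lmm_spec("y", fixed = character(), transform = "identity"), d)
  d2 <- d; d2$y <- d2$y * 7.3
  f2 <- fit_lmm(lmm_spec("y", fixed = character(), transform = "identity"), d2)
  expect_equal(repeatability(f)$R, repeatability(f2)$R, tolerance = 1e-6)
})

test_that("AIC backward selection keeps real effects and drops absent ones", {
  # strong year effect (3 residual SDs), no timing effect
  d <- simulate_trait_data(60, 4, 0.7, 1, mu = 1,
                           seasons = c("2014-15", "2015-16", "2016-17"),
                           season_shift = c(0, 3, -3), seed = 10)
  sel <- select_fixed_effects(lmm_spec("y", transform = "identity"), d)
  expect_true("year" %in% sel$spec$fixed)
  expect_false("year:timing" %in% sel$spec$fixed)
  # no fixed effects at all -> intercept-only model
  d0 <- simulate_trait_data(60, 4, 0.7, 1, mu = 1,
                            seasons = c("2014-15", "2015-16"), seed = 11)
  sel0 <- select_fixed_effects(lmm_spec("y", transform = "identity"), d0)
  expect_length(sel0$spec$fixed, 0)
})

test_that("parsimony rule prefers the smaller model within 2 AIC units", {
  # the smaller of two candidate structures wins when |dAIC| < 2; emulate by
  # checking the decision on data where timing is pure noise
  d <- simulate_trait_data(40, 4, 0.7, 1, seed = 12)
  full <- fit_lmm(lmm_spec("y", fixed = c("timing"), transform = "identity"), d)
  null <- fit_lmm(lmm_spec("y", fixed = character(), transform = "identity"), d)
  sel <- select_fixed_effects(lmm_spec("y", fixed = "timing",
                                       transform = "identity"), d)
  if (abs(full$aic - null$aic) < 2) expect_length(sel$spec$fixed, 0)
})

test_that("bootstrap is seeded, reproducible and carries percentile CIs", {
  d <- simulate_trait_data(40, 4, sqrt(0.4), sqrt(0.6), mu = 2, seed = 14)
  f <- fit_lmm(lmm_spec("y", fixed = character(), transform = "identity"), d)
  b1 <- bootstrap_R(f, n_boot = 100, seed = 42)
  b2 <- bootstrap_R(f, n_boot = 100, seed = 42)
  expect_identical(b1$se, b2$se)
  expect_identical(b1$ci, b2$ci)
  expect_true(b1$ci[1] < b1$R & b1$R < b1$ci[2])
  # n_boot = 0: point estimate only
  p <- bootstrap_R(f, n_boot = 0)
  expect_true(is.na(p$se))
})

test_that("unmodelled year effects inflate non-adjusted repeatability", {
  # year confounded with individual blocks (each bird in one season):
  # a strong year shift loads onto the between-individual variance when
  # the fixed effect is omitted
  d <- simulate_trait_data(60, 4, 0.5, 1, mu = 1,
                           seasons = c("a", "b", "c"),
                           season_shift = c(-2, 0, 2), seed = 15)
  both <- adjusted_vs_nonadjusted(lmm_spec("y", transform = "identity"), d)
  expect_gt(both$non_adjusted$R, both$adjusted$R)
  # without year effects the two agree closely
  d0 <- simulate_trait_data(100, 5, 0.5, 1, mu = 1,
                            seasons = c("a", "b"), seed = 16)
  both0 <- adjusted_vs_nonadjusted(lmm_spec("y", transform = "identity"), d0)
  expect_lt(abs(both0$non_adjusted$R - both0$adjusted$R), 0.05)
  expect_equal(nrow(both0$table), 2)
  expect_setequal(both0$table$model, c("adjusted", "non_adjusted"))
})
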