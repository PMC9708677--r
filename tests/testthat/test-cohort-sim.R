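test_that("effect_config validates its invariants", {
  expect_error(effect_config(n_subjects = 1), "at least 2")
  expect_error(effect_config(baseline_risk = 0), "0, 1")
  expect_error(effect_config(baseline_risk = 1.2), "0, 1")
  expect_error(effect_config(rr_nwu_per_pct = -0.5), "positive")
  expect_error(effect_config(growth_noise_sd = -1), "non-negative")
  expect_error(
    effect_config(covariate_distributions = list(nwu = list(median = -2))),
    "positive")
})

test_that("cohort simulation is deterministic under a fixed seed", {
  cfg <- effect_config(n_subjects = 500, seed = 123)
  expect_identical(suppressWarnings(simulate_cohort(cfg)),
                   suppressWarnings(simulate_cohort(cfg)))
})

test_that("cohort columns respect clinical ranges and the record schema", {
  co <- suppressWarnings(simulate_cohort(effect_config(n_subjects = 2000, seed = 5)))
  expect_equal(nrow(co), 2000)
  expect_true(all(co$aspects >= 0 & co$aspects <= 10))
  expect_true(all(co$nwu_pct >= 0))
  expect_true(all(co$pcore_ml >= 0))
  expect_true(all(co$fiv_ml >= 0))
  expect_true(all(co$onset_to_recanalization_min > co$onset_to_imaging_min))
  expect_equal(co$lesion_growth_ml, co$fiv_ml - co$pcore_ml)
  # eTICI 2c/3 defines successful reperfusion
  expect_equal(co$etici %in% c("2c", "3"), co$reperfusion_success)
  # good outcome is mRS90 <= 2 where mRS90 is observed, NA where missing
  obs <- !is.na(co$mrs90)
  expect_equal(co$good_outcome[obs], co$mrs90[obs] <= 2)
  expect_true(all(is.na(co$good_outcome[!obs])))
  expect_gt(sum(!obs), 0)
})

test_that("a null risk model reproduces the baseline rate", {
  n <- 20000
  co <- simulate_cohort(single_effect_config(n, seed = 77))
  # empirical rate within 3 SE of the analytic marginal probability
  se <- sqrt(0.16 * 0.84 / n)
  expect_lt(abs(mean(co$overestimated) - 0.16), 3 * se)
})

test_that("the empirical rate converges to the analytic marginal with effects on", {
  cfg <- effect_config(n_subjects = 50000, seed = 31)
  co <- suppressWarnings(simulate_cohort(cfg))
  analytic <- pmin(
    cfg$baseline_risk *
      cfg$rr_nwu_per_pct^(co$nwu_pct - cfg$nwu_ref) *
      cfg$rr_pcore_per_ml^(co$pcore_ml - cfg$pcore_ref) *
      cfg$rr_aspects_per_point^(co$aspects - cfg$aspects_ref), 1)
  p <- mean(analytic)
  se <- sqrt(p * (1 - p) / nrow(co))
  expect_lt(abs(mean(co$overestimated) - p), 3 * se)
})

test_that("consistency mode couples the flag to the recorded growth", {
  cfg <- effect_config(n_subjects = 5000, consistency = TRUE, seed = 9)
  co <- suppressWarnings(simulate_cohort(cfg))
  expect_identical(co$overestimated, co$lesion_growth_ml < -10)
  expect_gt(sum(co$overestimated), 0)
  # overestimation by > 10 mL is only possible when the core exceeds 10 mL
  expect_true(all(co$pcore_ml[co$overestimated] > 10))
})

test_that("independent mode draws growth from the stated linear model", {
  cfg <- effect_config(n_subjects = 20000, seed = 13)
  co <- suppressWarnings(simulate_cohort(cfg))
  g3 <- cubic_root_transform(co$lesion_growth_ml)
  mu <- cfg$growth_intercept + cfg$beta_nwu * co$nwu_pct +
    cfg$beta_pcore * co$pcore_ml + cfg$beta_aspects * co$aspects +
    cfg$beta_reperfusion * co$reperfusion_success
  resid <- g3 - mu
  expect_lt(abs(mean(resid)), 0.02)
  expect_lt(abs(sd(resid) - cfg$growth_noise_sd), 0.02)
})

test_that("excess probability clipping triggers a warning with a count", {
  cfg <- effect_config(n_subjects = 2000, baseline_risk = 0.9,
                       rr_pcore_per_ml = 1.05, seed = 2)
  expect_warning(simulate_cohort(cfg), "clipped")
})

test_that("cohorts round-trip through CSV losslessly", {
  path <- withr::local_tempfile(fileext = ".csv")
  co <- suppressWarnings(simulate_cohort(effect_config(n_subjects = 150, seed = 4)))
  write_cohort(co, path)
  co2 <- read_cohort(path)
  expect_equal(as.data.frame(co2), as.data.frame(co), tolerance = 1e-12)
  expect_identical(co2$etici, co$etici)
  expect_identical(co2$sex, co$sex)
})
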