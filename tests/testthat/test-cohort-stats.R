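test_that("fit_rr agrees with brute-force maximum likelihood on a small fixture", {
  co <- simulate_cohort(effect_config(n_subjects = 200, rr_nwu_per_pct = 0.92,
                                      rr_pcore_per_ml = 1.02,
                                      rr_aspects_per_point = 1, seed = 21))
  fit <- fit_rr(co, "overestimated", c("nwu_pct", "pcore_ml"))
  expect_false(fit$fallback)
  td <- tidy(fit)
  bf <- brute_force_logbin(co, "overestimated", c("nwu_pct", "pcore_ml"))
  expect_equal(td$estimate, bf, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("log-binomial fits recover generative relative risks at scale", {
  # per-unit RRs across the plausible effect range, one seeded cohort each
  cases <- list(
    list(rr = 0.90, on = "nwu"), list(rr = 0.94, on = "nwu"),
    list(rr = 1.00, on = "nwu"), list(rr = 1.02, on = "pcore"),
    list(rr = 1.28, on = "aspects"))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    cfg <- single_effect_config(
      50000, seed = 1000 + i,
      rr_nwu = if (cs$on == "nwu") cs$rr else 1,
      rr_pcore = if (cs$on == "pcore") cs$rr else 1,
      rr_aspects = if (cs$on == "aspects") cs$rr else 1)
    co <- simulate_cohort(cfg)
    pred <- switch(cs$on, nwu = "nwu_pct", pcore = "pcore_ml",
                   aspects = "aspects")
    td <- tidy(fit_rr(co, "overestimated", pred))
    expect_lt(abs(td$estimate - cs$rr), 0.02)
    expect_true(td$conf.low <= cs$rr && cs$rr <= td$conf.high)
  }
})

test_that("fit_rr rejects degenerate designs and single-class outcomes", {
  co <- suppressWarnings(simulate_cohort(effect_config(n_subjects = 300, seed = 8)))
  co$flat <- 1
  expect_error(fit_rr(co, "overestimated", "flat"), "constant")
  co$all_yes <- TRUE
  expect_error(fit_rr(co, "all_yes", "nwu_pct"), "single class")
  expect_error(fit_rr(co[1:5, ], "overestimated", "nwu_pct"), "too few")
})

test_that("complete-case rows are dropped and n_used reported", {
  co <- suppressWarnings(simulate_cohort(effect_config(n_subjects = 1000, seed = 14)))
  co$nwu_pct[1:100] <- NA
  td <- tidy(fit_rr(co, "overestimated", "nwu_pct"))
  expect_equal(td$n_used, 900)
  tl <- tidy(fit_linear(co, "nwu_pct"))
  expect_equal(tl$n_used, 900)
  # good-outcome models lose the subjects with missing mRS90
  tg <- tidy(fit_rr(co, "good_outcome", "aspects"))
  expect_equal(tg$n_used, sum(!is.na(co$good_outcome)))
})

test_that("odds-ratio mode differs from relative risk for a common outcome", {
  co <- suppressWarnings(simulate_cohort(effect_config(
    n_subjects = 20000, rr_aspects_per_point = 1.28, seed = 55)))
  rr <- tidy(fit_rr(co, "overestimated", "aspects"))$estimate
  or <- tidy(fit_rr(co, "overestimated", "aspects", family = "or"))$estimate
  expect_gt(or, rr)  # OR overstates the RR when risk is non-trivial
})

test_that("linear growth fits recover slopes, exactly so without noise", {
  cfg <- effect_config(n_subjects = 10000, beta_nwu = 0.06, beta_pcore = 0,
                       beta_aspects = 0, beta_reperfusion = 0,
                       growth_intercept = 2.2, growth_noise_sd = 0.5,
                       seed = 3)
  co <- simulate_cohort(cfg)
  td <- tidy(fit_linear(co, "nwu_pct"))
  expect_lt(abs(td$estimate - 0.06), 0.01)

  cfg0 <- effect_config(n_subjects = 500, beta_nwu = 0.06, beta_pcore = -0.01,
                        beta_aspects = -0.33, beta_reperfusion = -0.87,
                        growth_noise_sd = 0, seed = 3)
  co0 <- simulate_cohort(cfg0)
  td0 <- tidy(fit_linear(co0, c("nwu_pct", "pcore_ml", "aspects",
                                "reperfusion_success")))
  expect_equal(td0$estimate, c(0.06, -0.01, -0.33, -0.87),
               tolerance = 1e-8, ignore_attr = TRUE)

  # constant response: all slopes numerically zero
  co0$lesion_growth_ml <- 27
  tdc <- tidy(fit_linear(co0, "nwu_pct"))
  expect_equal(tdc$estimate, 0, tolerance = 1e-10)
})

test_that("build_multivariable keeps univariable-significant and forced terms", {
  uni <- tibble::tibble(
    term = c("a", "b", "c"), predictor = c("a", "b", "c"),
    estimate = 1, conf.low = 1, conf.high = 1,
    p.value = c(0.03, 0.20, 0.001), n_used = 100,
    model_tag = "univariable", fallback = FALSE)
  expect_equal(build_multivariable(uni), c("a", "c"))
  expect_equal(build_multivariable(uni, force = "sex"), c("a", "c", "sex"))
  uni$p.value <- c(0.3, 0.4, 0.5)
  expect_warning(sel <- build_multivariable(uni), "No univariable")
  expect_length(sel, 0)
})

test_that("the univariable screen finds the generative effects and only them", {
  co <- suppressWarnings(simulate_cohort(effect_config(n_subjects = 20000, seed = 17)))
  preds <- c("age", "sex", "nihss", "aspects", "pcore_ml", "nwu_pct")
  uni <- screen_univariable(co, "overestimated", preds, type = "rr")
  sel <- build_multivariable(uni)
  expect_true(all(c("aspects", "pcore_ml", "nwu_pct") %in% sel))
  expect_false(any(c("age", "sex", "nihss") %in% sel))
})

test_that("stratified sensitivity assigns the cutoff to the upper stratum", {
  co <- suppressWarnings(simulate_cohort(effect_config(n_subjects = 400, seed = 29)))
  # place pCore around the boundary deterministically
  co$pcore_ml <- rep(c(10, 49.9, 50, 70), each = 100)
  res <- stratified_sensitivity(co, "overestimated", "nwu_pct")
  ns <- unique(res[c("stratum", "n_stratum")])
  expect_equal(ns$n_stratum[ns$stratum == "pcore_lt_cutoff"], 200)
  expect_equal(ns$n_stratum[ns$stratum == "pcore_ge_cutoff"], 200)

  co$pcore_ml <- 10
  expect_error(stratified_sensitivity(co, "overestimated", "nwu_pct"),
               "non-empty")
})

test_that("per-stratum fits recover stratum-specific effects", {
  lo <- simulate_cohort(single_effect_config(20000, seed = 61, rr_nwu = 0.90))
  hi <- simulate_cohort(single_effect_config(20000, seed = 62, rr_nwu = 1.0))
  lo$pcore_ml <- pmin(lo$pcore_ml, 49)
  hi$pcore_ml <- 50 + hi$pcore_ml
  co <- dplyr::bind_rows(lo, hi)
  res <- stratified_sensitivity(co, "overestimated", "nwu_pct")
  est <- setNames(res$estimate, res$stratum)
  expect_lt(abs(est[["pcore_lt_cutoff"]] - 0.90), 0.02)
  expect_lt(abs(est[["pcore_ge_cutoff"]] - 1.0), 0.02)
})

test_that("describe_cohort summarises by distribution shape and flags shifts", {
  set.seed(99)
  toy <- tibble::tibble(
    grp = rep(c(FALSE, TRUE), each = 200),
    gauss = rnorm(400, 50, 5),
    skewed = rexp(400, 0.2),
    shifted = c(rnorm(200, 10, 3), rnorm(200, 15, 3)),
    flag = runif(400) < 0.3)
  d <- describe_cohort(toy, group = "grp")
  expect_equal(unique(d$distribution[d$variable == "gauss"]), "normal")
  expect_equal(unique(d$distribution[d$variable == "skewed"]), "non-normal")
  expect_equal(unique(d$distribution[d$variable == "flag"]), "categorical")
  # identical-law variables should not reject; a 5-unit shift must
  expect_gt(d$p_value[d$variable == "gauss"][1], 0.05)
  expect_lt(d$p_value[d$variable == "shifted"][1], 0.05)

  toy$grp <- FALSE
  expect_error(describe_cohort(toy, group = "grp"), "2 observed levels")
})

test_that("describe_cohort reports per-variable n under missingness", {
  co <- suppressWarnings(simulate_cohort(effect_config(n_subjects = 400, seed = 44)))
  d <- describe_cohort(co)
  mrs <- d[d$variable == "mrs90", ]
  expect_true(all(mrs$n_missing > 0))
  expect_equal(mrs$n + mrs$n_missing,
               as.integer(table(co$overestimated)[c("FALSE", "TRUE")]),
               ignore_attr = TRUE)
})
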