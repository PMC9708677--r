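#' Generative configuration for a simulated stroke cohort
#'
#' Bundles the ground-truth effect sizes and sampling laws from which
#' [simulate_cohort()] draws a cohort of endovascular-treatment candidates.
#' The binary outcomes (core overestimation, 90-day functional independence)
#' follow multiplicative relative-risk (log-link) models, so that the RR a
#' log-binomial regression recovers is exactly the generative parameter;
#' cubic-root lesion growth follows a linear model with Gaussian residuals.
#'
#' Default effect sizes are the adjusted estimates a cohort of this kind
#' exhibits: per-%NWU RR 0.94, per-mL pCore RR 1.02 and per-point ASPECTS RR
#' 1.28 on overestimation (baseline risk 0.16 at the reference covariates);
#' growth slopes 0.06 per %NWU, -0.33 per ASPECTS point, -0.01 per mL pCore
#' and -0.87 for successful reperfusion on the cube-root scale. Reference
#' covariate values are cohort medians (NWU 7.2%, pCore 11.9 mL, ASPECTS 7)
#' so `baseline_risk` is the risk of a median patient.
#'
#' Covariate sampling laws (overridable via `covariate_distributions`) are
#' chosen to reproduce typical admission-imaging summaries: NWU and pCore are
#' right-skewed exponentials with medians 7.2% and 11.9 mL, ASPECTS is
#' Binomial(10, 0.72) (median 7), age is a truncated normal around the
#' mid-70s, NIHSS a rounded normal around 15. The pCore support is truncated
#' at `covariate_distributions$pcore$max` (default 100 mL, reflecting that
#' very large cores rarely reach endovascular treatment), which also keeps
#' the unbounded log-link risk inside \[0, 1\] for all but a negligible
#' fraction of subjects; any residual clipping is counted and warned about.
#'
#' @param n_subjects Cohort size (>= 2). Default 284.
#' @param baseline_risk Overestimation probability at the reference
#'   covariates, in (0, 1).
#' @param rr_nwu_per_pct,rr_pcore_per_ml,rr_aspects_per_point Multiplicative
#'   risk ratios per covariate unit for core overestimation (> 0).
#' @param nwu_ref,pcore_ref,aspects_ref Reference covariate values at which
#'   `baseline_risk` applies.
#' @param growth_intercept,beta_nwu,beta_pcore,beta_aspects,beta_reperfusion
#'   Coefficients of the cube-root lesion-growth linear model.
#' @param growth_noise_sd Residual SD on the cube-root scale (> 0).
#' @param baseline_good Probability of 90-day functional independence (mRS
#'   0-2) at the reference covariates.
#' @param rr_age_good,rr_nihss_good,rr_aspects_good,rr_reperfusion_good
#'   Risk ratios of the good-outcome model (per year, per NIHSS point, per
#'   ASPECTS point, and for successful reperfusion).
#' @param age_ref,nihss_ref Reference age and NIHSS for the good-outcome
#'   model.
#' @param covariate_distributions Named list of sampling laws; see Details.
#'   Partial overrides are merged over the defaults.
#' @param consistency If `TRUE`, lesion growth and the overestimation flag
#'   are made mutually consistent (growth < -10 mL iff flagged, via
#'   truncated-normal sampling on the cube-root scale). If `FALSE` (default)
#'   the two outcomes are drawn independently from their respective models,
#'   so each is individually faithful to its generative law but the flag is
#'   not a deterministic function of the recorded growth.
#' @param seed RNG seed (`NULL` = leave RNG state alone).
#'
#' @return An object of class `effect_config`.
#' @export
effect_config <- function(n_subjects = 284,
                          baseline_risk = 0.16,
                          rr_nwu_per_pct = 0.94,
                          rr_pcore_per_ml = 1.02,
                          rr_aspects_per_point = 1.28,
                          nwu_ref = 7.2, pcore_ref = 11.9, aspects_ref = 7,
                          growth_intercept = 5.07,
                          beta_nwu = 0.06, beta_pcore = -0.01,
                          beta_aspects = -0.33, beta_reperfusion = -0.87,
                          growth_noise_sd = 0.5,
                          baseline_good = 0.25,
                          rr_age_good = 0.97, rr_nihss_good = 0.93,
                          rr_aspects_good = 1.2, rr_reperfusion_good = 1.61,
                          age_ref = 76.5, nihss_ref = 15,
                          covariate_distributions = list(),
                          consistency = FALSE,
                          seed = NULL) {
  if (n_subjects < 2) abort("`n_subjects` must be at least 2.")
  if (!(baseline_risk > 0 && baseline_risk < 1)) {
    abort("`baseline_risk` must lie in (0, 1).")
  }
  if (!(baseline_good > 0 && baseline_good < 1)) {
    abort("`baseline_good` must lie in (0, 1).")
  }
  rrs <- c(rr_nwu_per_pct, rr_pcore_per_ml, rr_aspects_per_point,
           rr_age_good, rr_nihss_good, rr_aspects_good, rr_reperfusion_good)
  if (any(rrs <= 0)) abort("All risk ratios must be strictly positive.")
  if (growth_noise_sd < 0) abort("`growth_noise_sd` must be non-negative.")
  defaults <- list(
    age = list(mean = 73.5, sd = 12, min = 18, max = 100),
    p_female = 0.48,
    nihss = list(mean = 15, sd = 6, min = 0, max = 42),
    aspects = list(size = 10, prob = 0.72),
    nwu = list(median = 7.2),
    pcore = list(median = 11.9, max = 100),
    penumbra = list(meanlog = log(72), sdlog = 0.6),
    onset_imaging = list(meanlog = log(192), sdlog = 0.8),
    imaging_recan = list(meanlog = log(90), sdlog = 0.4),
    p_alteplase = 0.55,
    p_reperfusion = 0.493,
    p_missing_mrs90 = 0.25
  )
  cd <- utils::modifyList(defaults, covariate_distributions)
  if (cd$aspects$size != 10) abort("ASPECTS support is 0-10.")
  if (cd$nwu$median <= 0 || cd$pcore$median <= 0) {
    abort("NWU and pCore medians must be positive.")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), baseline_risk = baseline_risk,
         rr_nwu_per_pct = rr_nwu_per_pct, rr_pcore_per_ml = rr_pcore_per_ml,
         rr_aspects_per_point = rr_aspects_per_point,
         nwu_ref = nwu_ref, pcore_ref = pcore_ref, aspects_ref = aspects_ref,
         growth_intercept = growth_intercept, beta_nwu = beta_nwu,
         beta_pcore = beta_pcore, beta_aspects = beta_aspects,
         beta_reperfusion = beta_reperfusion,
         growth_noise_sd = growth_noise_sd,
         baseline_good = baseline_good, rr_age_good = rr_age_good,
         rr_nihss_good = rr_nihss_good, rr_aspects_good = rr_aspects_good,
         rr_reperfusion_good = rr_reperfusion_good,
         age_ref = age_ref, nihss_ref = nihss_ref,
         covariate_distributions = cd, consistency = isTRUE(consistency),
         seed = seed),
    class = "effect_config"
  )
}

# Two-sided truncated-normal draw by inverse CDF; bounds may be -Inf/Inf.
# Works in log-probability space so that intervals many SDs into a tail
# (which arise when the flag and growth models disagree) stay exact.
rtruncnorm_u <- function(u, mean, sd, lower, upper) {
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  lp_lo <- pnorm(lower, mean, sd, log.p = TRUE)
  lp_hi <- pnorm(upper, mean, sd, log.p = TRUE)
  # log(p_lo + u * (p_hi - p_lo)) without leaving log space
  lp <- lp_lo + log1p(u * expm1(lp_hi - lp_lo))
  out <- qnorm(lp, mean, sd, log.p = TRUE)
  # if the tail mass underflows entirely, the truncation dominates: draw
  # unconstrained and clamp into the interval
  bad <- !is.finite(out)
  if (any(bad)) {
    out[bad] <- qnorm(u[bad], mean = if (length(mean) > 1) mean[bad] else mean,
                      sd = sd)
  }
  pmin(pmax(out, lower), upper)
}

#' Simulate a stroke cohort with known outcome structure
#'
#' Draws `n_subjects` patient records whose covariates follow the sampling
#' laws in the [effect_config()] and whose outcomes follow its generative
#' models:
#'
#' * `P(overestimated) = clip(baseline_risk * rr_nwu^(NWU - NWU_ref) *
#'   rr_pcore^(pCore - pCore_ref) * rr_aspects^(ASPECTS - ASPECTS_ref), 0, 1)`
#' * cube-root lesion growth `= intercept + beta_nwu * NWU + beta_pcore *
#'   pCore + beta_aspects * ASPECTS + beta_reperfusion * reperfusion + eps`,
#'   `eps ~ N(0, growth_noise_sd)`
#' * `P(mRS90 0-2) = clip(baseline_good * rr_age^(age - age_ref) * ...)`.
#'
#' The final infarct volume is reconstructed as `pCore + growth`, floored at
#' 0 (an infarct cannot have negative volume); `lesion_growth_ml` is the
#' difference after flooring. If more than 1% of subjects need probability
#' clipping in either risk model, a warning reports the count: a log-link
#' risk model is unbounded and the covariate supports are expected to keep
#' it inside \[0, 1\].
#'
#' @param config An [effect_config()].
#' @return A tibble with one row per subject: `subject_id`, `age`, `sex`,
#'   `nihss`, `aspects`, `nwu_pct`, `pcore_ml`, `penumbra_ml`,
#'   `iv_alteplase`, `onset_to_imaging_min`, `onset_to_recanalization_min`,
#'   `etici`, `reperfusion_success`, `fiv_ml`, `lesion_growth_ml`,
#'   `overestimated`, `mrs90`, `good_outcome`.
#' @export
#' @examples
#' cohort <- simulate_cohort(effect_config(n_subjects = 100, seed = 7))
#' dplyr::count(cohort, overestimated)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "effect_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  cd <- config$covariate_distributions

  age <- pmin(pmax(rnorm(n, cd$age$mean, cd$age$sd), cd$age$min), cd$age$max)
  sex <- factor(ifelse(runif(n) < cd$p_female, "female", "male"),
                levels = c("female", "male"))
  nihss <- pmin(pmax(round(rnorm(n, cd$nihss$mean, cd$nihss$sd)),
                     cd$nihss$min), cd$nihss$max)
  aspects <- rbinom(n, cd$aspects$size, cd$aspects$prob)
  nwu <- stats::rexp(n, rate = log(2) / cd$nwu$median)
  rate_p <- log(2) / cd$pcore$median
  pcore <- qexp(runif(n) * pexp(cd$pcore$max, rate_p), rate_p)
  penumbra <- rlnorm(n, cd$penumbra$meanlog, cd$penumbra$sdlog)
  onset_img <- rlnorm(n, cd$onset_imaging$meanlog, cd$onset_imaging$sdlog)
  onset_recan <- onset_img +
    rlnorm(n, cd$imaging_recan$meanlog, cd$imaging_recan$sdlog)
  alteplase <- runif(n) < cd$p_alteplase
  reperf <- runif(n) < cd$p_reperfusion
  etici <- factor(
    ifelse(reperf,
           sample(c("2c", "3"), n, replace = TRUE),
           sample(c("0", "1", "2a", "2b"), n, replace = TRUE,
                  prob = c(0.15, 0.1, 0.25, 0.5))),
    levels = c("0", "1", "2a", "2b", "2c", "3"), ordered = TRUE)

  risk_over <- config$baseline_risk *
    config$rr_nwu_per_pct^(nwu - config$nwu_ref) *
    config$rr_pcore_per_ml^(pcore - config$pcore_ref) *
    config$rr_aspects_per_point^(aspects - config$aspects_ref)
  n_clip_over <- sum(risk_over > 1)
  overest <- rbinom(n, 1, pmin(risk_over, 1)) == 1

  mu <- config$growth_intercept + config$beta_nwu * nwu +
    config$beta_pcore * pcore + config$beta_aspects * aspects +
    config$beta_reperfusion * reperf
  thr <- cubic_root_transform(-10)
  if (config$consistency) {
    # overestimation by > 10 mL requires pCore > 10 mL (FIV >= 0)
    overest <- overest & (pcore > 10)
    lo <- cubic_root_transform(-pcore)
    u <- runif(n)
    g3 <- ifelse(overest,
                 # strict inequality: flagged growth must stay below -10 mL
                 rtruncnorm_u(u, mu, config$growth_noise_sd, lo, thr - 1e-9),
                 rtruncnorm_u(u, mu, config$growth_noise_sd, thr, Inf))
  } else {
    g3 <- rnorm(n, mu, config$growth_noise_sd)
  }
  growth <- g3^3
  fiv <- pmax(0, pcore + growth)
  growth <- fiv - pcore

  risk_good <- config$baseline_good *
    config$rr_age_good^(age - config$age_ref) *
    config$rr_nihss_good^(nihss - config$nihss_ref) *
    config$rr_aspects_good^(aspects - config$aspects_ref) *
    config$rr_reperfusion_good^(reperf)
  n_clip_good <- sum(risk_good > 1)
  good <- rbinom(n, 1, pmin(risk_good, 1)) == 1
  mrs90 <- ifelse(good, sample(0:2, n, replace = TRUE),
                  sample(3:6, n, replace = TRUE))
  mrs90[runif(n) < cd$p_missing_mrs90] <- NA_integer_
  good_outcome <- mrs90 <= 2  # NA when mRS90 is missing (complete-case later)

  if (n_clip_over > 0.01 * n) {
    warn(sprintf(
      "Overestimation risk model left [0, 1] for %d of %d subjects (clipped).",
      n_clip_over, n))
  }
  if (n_clip_good > 0.01 * n) {
    warn(sprintf(
      "Good-outcome risk model left [0, 1] for %d of %d subjects (clipped).",
      n_clip_good, n))
  }

  tibble(
    subject_id = seq_len(n),
    age = age, sex = sex, nihss = nihss, aspects = aspects,
    nwu_pct = nwu, pcore_ml = pcore, penumbra_ml = penumbra,
    iv_alteplase = alteplase,
    onset_to_imaging_min = onset_img,
    onset_to_recanalization_min = onset_recan,
    etici = etici, reperfusion_success = reperf,
    fiv_ml = fiv, lesion_growth_ml = growth,
    overestimated = overest, mrs90 = mrs90,
    good_outcome = as.logical(good_outcome)
  )
}

#' Write / read a cohort table as CSV
#'
#' `write_cohort()` writes the patient-record tibble produced by
#' [simulate_cohort()] (or assembled from real measurements) to CSV;
#' `read_cohort()` reads it back with the column types of the record schema
#' restored (factors, logicals, integers), so a round trip is lossless.
#'
#' @param cohort A patient-record tibble.
#' @param path CSV file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a
#'   tibble.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  out <- as_tibble(df)
  if ("sex" %in% names(out)) {
    out$sex <- factor(out$sex, levels = c("female", "male"))
  }
  if ("etici" %in% names(out)) {
    out$etici <- factor(as.character(out$etici),
                        levels = c("0", "1", "2a", "2b", "2c", "3"),
                        ordered = TRUE)
  }
  for (col in c("iv_alteplase", "reperfusion_success", "overestimated",
                "good_outcome")) {
    if (col %in% names(out)) out[[col]] <- as.logical(out[[col]])
  }
  for (col in c("subject_id", "nihss", "aspects", "mrs90")) {
    if (col %in% names(out)) out[[col]] <- as.integer(out[[col]])
  }
  out
}
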