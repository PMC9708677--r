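#' Pipeline configuration
#'
#' Collects every threshold and model option of the measurement and analysis
#' pipeline in one validated object, so a run is fully described by (config,
#' inputs, seed) and its outputs can embed a config hash for provenance.
#'
#' @param hu_lo,hu_hi Inclusive parenchymal HU window; defaults 20 and 80.
#' @param rcbf_threshold Predicted-core rCBF threshold (%), in (0, 100];
#'   default 20.
#' @param tmax_threshold Hypoperfusion Tmax threshold (s); default 6.
#' @param tmax_inclusive Count voxels exactly at the Tmax threshold?
#'   Default `TRUE`.
#' @param overestimation_threshold_ml Growth threshold below which the core
#'   is scored overestimated; default -10 mL (strict inequality).
#' @param stratify_cutoff_ml pCore cutoff of the sensitivity analysis;
#'   default 50 mL.
#' @param alpha Significance threshold for model building; default 0.05.
#' @param statistic ROI density statistic, `"mean"` or `"median"`.
#' @param model_family `"rr"` (log-binomial) or `"or"` (logistic).
#' @param seed Seed recorded in, and used by, every stochastic stage.
#' @param out_dir Optional output directory for written tables.
#'
#' @return An object of class `pipeline_config` with a `config_hash` field.
#' @export
pipeline_config <- function(hu_lo = 20, hu_hi = 80,
                            rcbf_threshold = 20,
                            tmax_threshold = 6, tmax_inclusive = TRUE,
                            overestimation_threshold_ml = -10,
                            stratify_cutoff_ml = 50,
                            alpha = 0.05,
                            statistic = c("mean", "median"),
                            model_family = c("rr", "or"),
                            seed = NULL, out_dir = NULL) {
  statistic <- match.arg(statistic)
  model_family <- match.arg(model_family)
  if (hu_lo >= hu_hi) abort("HU window must satisfy hu_lo < hu_hi.")
  if (rcbf_threshold <= 0 || rcbf_threshold > 100) {
    abort("`rcbf_threshold` must lie in (0, 100].")
  }
  if (tmax_threshold < 0) abort("`tmax_threshold` must be non-negative.")
  if (stratify_cutoff_ml <= 0) abort("`stratify_cutoff_ml` must be positive.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  cfg <- list(hu_lo = hu_lo, hu_hi = hu_hi,
              rcbf_threshold = rcbf_threshold,
              tmax_threshold = tmax_threshold,
              tmax_inclusive = isTRUE(tmax_inclusive),
              overestimation_threshold_ml = overestimation_threshold_ml,
              stratify_cutoff_ml = stratify_cutoff_ml,
              alpha = alpha, statistic = statistic,
              model_family = model_family,
              seed = seed, out_dir = out_dir)
  cfg$config_hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  structure(cfg, class = "pipeline_config")
}

#' Measure one imaging case
#'
#' Runs the full per-case measurement chain on one set of images: net water
#' uptake from the admission CT and lesion mask (mirror-ROI densitometry),
#' predicted core and penumbra from the perfusion maps, final infarct volume
#' from the follow-up mask, lesion growth and the overestimation flag. If
#' the follow-up mask is absent, NWU and the perfusion volumes are still
#' emitted and the growth fields are `NA`.
#'
#' @param case Either a `phantom_bundle`, a directory written by
#'   [write_phantom()], or a list with elements `admission_ct`
#'   ([ct_volume()]), `ischemic_mask`, `perfusion` ([perfusion_maps()]) and
#'   optionally `fiv_mask`.
#' @param config A [pipeline_config()].
#' @param case_id Identifier embedded in the output row.
#'
#' @return A one-row tibble merging the densitometry and volumetric results,
#'   with provenance columns `case_id`, `config_hash`, `seed` and
#'   `nwuct_version`.
#' @export
#' @examples
#' b <- generate_phantom(phantom_spec(noise_sd_hu = 0))
#' run_case(b)
run_case <- function(case, config = pipeline_config(), case_id = "case") {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(case) && length(case) == 1L) case <- read_phantom(case)
  ct <- case$admission_ct
  maps <- case$perfusion
  mask <- case$ischemic_mask
  if (is.null(ct) || is.null(maps) || is.null(mask)) {
    abort("`case` must provide admission_ct, perfusion and ischemic_mask.")
  }
  if (!identical(dim(mask), dim(ct$voxels))) {
    abort("Geometry mismatch between ischemic_mask and admission_ct.")
  }
  if (!identical(dim(maps$rcbf_pct), dim(ct$voxels))) {
    abort("Geometry mismatch between perfusion maps and admission_ct.")
  }

  nwu <- compute_nwu(ct, mask, hu_window = c(config$hu_lo, config$hu_hi),
                     statistic = config$statistic)
  pcore <- compute_pcore(maps, config$rcbf_threshold)
  pen <- compute_penumbra(maps, pcore, config$tmax_threshold,
                          inclusive = config$tmax_inclusive)

  if (!is.null(case$fiv_mask)) {
    if (!identical(dim(case$fiv_mask), dim(ct$voxels))) {
      abort("Geometry mismatch between fiv_mask and admission_ct.")
    }
    fiv <- volume_ml(case$fiv_mask, ct$spacing_mm)
    growth <- lesion_growth(fiv, pcore)
    overest <- classify_overestimation(
      growth, config$overestimation_threshold_ml)
  } else {
    fiv <- NA_real_
    growth <- NA_real_
    overest <- NA
  }

  dplyr::bind_cols(
    tibble(case_id = case_id),
    nwu,
    tibble(pcore_ml = pcore),
    pen,
    tibble(
      fiv_ml = fiv, lesion_growth_ml = growth, overestimated = overest,
      config_hash = config$config_hash,
      seed = config$seed %||% NA_integer_,
      nwuct_version = as.character(packageVersion("nwuct"))
    )
  )
}

# default candidate predictors of the study-level models
study_predictors <- function(cohort) {
  intersect(
    c("age", "sex", "nihss", "aspects", "pcore_ml", "nwu_pct",
      "iv_alteplase", "onset_to_imaging_min", "onset_to_recanalization_min",
      "reperfusion_success"),
    names(cohort))
}

#' Run the full study-level analysis on a cohort
#'
#' Produces the complete set of study tables from a cohort of patient
#' records (simulated via [simulate_cohort()] if none is supplied): the
#' descriptive table stratified by core overestimation; univariable and
#' multivariable relative-risk tables for core overestimation and for good
#' functional outcome (with sex forced into the good-outcome multivariable
#' model); univariable and multivariable linear models of cube-root lesion
#' growth; and the pCore-stratified sensitivity screen. All runs are
#' deterministic given the config seed, and every table can be written to
#' `config$out_dir` as CSV alongside a JSON bundle carrying the config hash
#' and seed.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional patient-record tibble; simulated from `effect`
#'   when absent.
#' @param effect An [effect_config()] used when `cohort` is `NULL`; its
#'   seed is taken from `config$seed` unless already set.
#'
#' @return An object of class `study_results`: a list of tibbles
#'   (`descriptive`, `overestimation_univariable`,
#'   `overestimation_multivariable`, `good_outcome_univariable`,
#'   `good_outcome_multivariable`, `growth_univariable`,
#'   `growth_multivariable`, `stratified_overestimation`) plus `cohort`,
#'   `config` and provenance.
#' @export
run_study <- function(config = pipeline_config(), cohort = NULL,
                      effect = effect_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    if (is.null(effect$seed)) effect$seed <- config$seed
    cohort <- simulate_cohort(effect)
  }
  if (nrow(cohort) < 2L) abort("Cohort must contain at least 2 cases.")
  preds <- study_predictors(cohort)

  descriptive <- describe_cohort(cohort, group = "overestimated",
                                 alpha = config$alpha)

  uni_over <- screen_univariable(cohort, "overestimated", preds,
                                 type = "rr", family = config$model_family)
  sel_over <- build_multivariable(uni_over, alpha = config$alpha)
  multi_over <- if (length(sel_over)) {
    tidy(fit_rr(cohort, "overestimated", sel_over,
                family = config$model_family, model_tag = "multivariable"))
  } else {
    uni_over[0, ]
  }

  uni_good <- screen_univariable(cohort, "good_outcome", preds,
                                 type = "rr", family = config$model_family)
  sel_good <- build_multivariable(uni_good, alpha = config$alpha,
                                  force = "sex")
  multi_good <- tidy(fit_rr(cohort, "good_outcome", sel_good,
                            family = config$model_family,
                            model_tag = "multivariable"))

  uni_growth <- screen_univariable(cohort, "lesion_growth_ml", preds,
                                   type = "linear")
  sel_growth <- build_multivariable(uni_growth, alpha = config$alpha)
  multi_growth <- if (length(sel_growth)) {
    tidy(fit_linear(cohort, sel_growth, model_tag = "multivariable"))
  } else {
    uni_growth[0, ]
  }

  strat <- stratified_sensitivity(cohort, "overestimated", preds,
                                  cutoff_ml = config$stratify_cutoff_ml,
                                  type = "rr", family = config$model_family)

  res <- structure(
    list(descriptive = descriptive,
         overestimation_univariable = uni_over,
         overestimation_multivariable = multi_over,
         good_outcome_univariable = uni_good,
         good_outcome_multivariable = multi_good,
         growth_univariable = uni_growth,
         growth_multivariable = multi_growth,
         stratified_overestimation = strat,
         cohort = cohort,
         config = config,
         seed = config$seed,
         config_hash = config$config_hash,
         nwuct_version = as.character(packageVersion("nwuct"))),
    class = "study_results"
  )
  if (!is.null(config$out_dir)) write_study(res, config$out_dir)
  res
}

#' @export
print.study_results <- function(x, ...) {
  cat("<study_results> cohort n = ", nrow(x$cohort),
      ", config ", x$config_hash, "\n", sep = "")
  cat("Tables:",
      paste(setdiff(names(x), c("cohort", "config", "seed", "config_hash",
                                "nwuct_version")),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write study tables to disk
#'
#' Writes each table of a [run_study()] result as CSV and a `study.json`
#' bundle (all tables plus config hash, seed and package version) for
#' machine consumption.
#'
#' @param results A `study_results` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(results, dir) {
  stopifnot(inherits(results, "study_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- setdiff(names(results), c("cohort", "config", "seed",
                                      "config_hash", "nwuct_version"))
  for (tb in tables) {
    utils::write.csv(as.data.frame(results[[tb]]),
                     file.path(dir, paste0(tb, ".csv")), row.names = FALSE)
  }
  write_cohort(results$cohort, file.path(dir, "cohort.csv"))
  bundle <- c(
    lapply(results[tables], function(d) as.data.frame(d)),
    list(config = unclass(results$config),
         seed = results$seed, config_hash = results$config_hash,
         nwuct_version = results$nwuct_version))
  jsonlite::write_json(bundle, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(dir)
}
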