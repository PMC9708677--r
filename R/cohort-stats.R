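#' Fit a relative-risk (log-binomial) regression
#'
#' Fits a binomial GLM with a log link, whose exponentiated coefficients are
#' relative risks per predictor unit, with Wald 95% confidence intervals.
#' This is the only binary-outcome model whose coefficients are literally
#' RRs; a logistic fit would yield odds ratios, which overstate RRs when the
#' outcome is common. An odds-ratio mode (`family = "or"`) is provided for
#' comparison and flagged as such in the output.
#'
#' Log-binomial likelihoods are awkward near the boundary (fitted risks
#' approaching 1); if the fit fails or does not converge, the model falls
#' back to a modified Poisson regression (log-link Poisson with
#' heteroskedasticity-robust sandwich variance), a standard consistent RR
#' estimator, and the result is flagged `fallback = TRUE`.
#'
#' Rows with a missing value in the outcome or any predictor are dropped
#' (complete-case analysis); `n_used` records what remained.
#'
#' @param data A cohort data frame.
#' @param outcome Name of a binary (logical or 0/1) outcome column with both
#'   classes present.
#' @param predictors Character vector of predictor column names.
#' @param conf_level Confidence level for Wald intervals; default 0.95.
#' @param family `"rr"` (log-binomial, default) or `"or"` (logistic, odds
#'   ratios).
#' @param model_tag Label stored with the results, e.g. `"univariable"` or
#'   `"multivariable"`. Defaults by predictor count.
#'
#' @return An object of class `rr_fit`. Use [tidy()] for the per-term
#'   estimates and [glance()] for the fit summary.
#' @export
#' @examples
#' cohort <- simulate_cohort(effect_config(n_subjects = 2000, seed = 1))
#' tidy(fit_rr(cohort, "overestimated", c("nwu_pct", "aspects")))
fit_rr <- function(data, outcome, predictors, conf_level = 0.95,
                   family = c("rr", "or"), model_tag = NULL) {
  family <- match.arg(family)
  model_tag <- model_tag %||%
    if (length(predictors) > 1L) "multivariable" else "univariable"
  dat <- check_model_frame(data, outcome, predictors, min_extra = 10L)
  y <- as.numeric(dat[[outcome]])
  if (!all(y %in% c(0, 1))) {
    abort(sprintf("Outcome '%s' must be binary (logical or 0/1).", outcome))
  }
  if (length(unique(y)) < 2L) {
    abort(sprintf("Outcome '%s' has a single class; nothing to model.",
                  outcome))
  }
  fml <- as.formula(paste(outcome, "~", paste(predictors, collapse = " + ")))
  dat[[outcome]] <- y

  fallback <- FALSE
  if (family == "or") {
    fit <- glm(fml, data = dat, family = binomial("logit"))
    vc <- vcov(fit)
  } else {
    X <- stats::model.matrix(fml, dat)
    start <- c(log(max(mean(y), 1e-6)), rep(0, ncol(X) - 1L))
    fit <- tryCatch(
      suppressWarnings(glm(fml, data = dat, family = binomial("log"),
                           start = start, control = list(maxit = 100))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      fallback <- TRUE
      fit <- glm(fml, data = dat, family = poisson("log"))
      vc <- sandwich::vcovHC(fit, type = "HC0")
    } else {
      vc <- vcov(fit)
    }
  }

  structure(
    list(model = fit, vcov = vc, outcome = outcome, predictors = predictors,
         n_used = nrow(dat), conf_level = conf_level, family = family,
         fallback = fallback, model_tag = model_tag),
    class = "rr_fit"
  )
}

#' Fit a linear model for (cube-root) lesion growth
#'
#' Ordinary least squares on a transformed response, by default the signed
#' cube root of `lesion_growth_ml` (the transform that symmetrises the
#' heavily skewed growth distribution). Coefficients are reported with
#' t-based confidence intervals. Complete-case as in [fit_rr()].
#'
#' @inheritParams fit_rr
#' @param response Response column; default `"lesion_growth_ml"`.
#' @param transform Function applied to the response before fitting; default
#'   [cubic_root_transform()]. Use `identity` for an untransformed fit.
#'
#' @return An object of class `growth_fit`, with [tidy()] and [glance()]
#'   methods.
#' @export
fit_linear <- function(data, predictors, response = "lesion_growth_ml",
                       transform = cubic_root_transform, conf_level = 0.95,
                       model_tag = NULL) {
  model_tag <- model_tag %||%
    if (length(predictors) > 1L) "multivariable" else "univariable"
  dat <- check_model_frame(data, response, predictors, min_extra = 10L)
  dat[[".response"]] <- transform(dat[[response]])
  if (!all(is.finite(dat[[".response"]]))) {
    abort("Transformed response contains non-finite values.")
  }
  fml <- as.formula(paste(".response ~",
                          paste(predictors, collapse = " + ")))
  fit <- lm(fml, data = dat)
  structure(
    list(model = fit, outcome = response, predictors = predictors,
         n_used = nrow(dat), conf_level = conf_level, model_tag = model_tag),
    class = "growth_fit"
  )
}

# Complete-case model frame with degeneracy checks shared by the fitters.
check_model_frame <- function(data, outcome, predictors, min_extra = 10L) {
  cols <- c(outcome, predictors)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("Column(s) not found: ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  dat <- data[complete.cases(data[cols]), cols, drop = FALSE]
  if (nrow(dat) < length(predictors) + min_extra) {
    abort(sprintf("Only %d complete cases for %d predictor(s); too few to fit.",
                  nrow(dat), length(predictors)))
  }
  for (p in predictors) {
    v <- dat[[p]]
    if (length(unique(v)) < 2L) {
      abort(sprintf("Predictor '%s' is constant in the complete cases.", p))
    }
  }
  dat
}

#' @export
print.rr_fit <- function(x, ...) {
  lab <- if (x$family == "or") "odds-ratio (logistic)" else "relative-risk (log-binomial)"
  if (x$fallback) lab <- paste0(lab, ", robust-Poisson fallback")
  cat("<rr_fit> ", lab, " model of '", x$outcome, "', n = ", x$n_used,
      " (", x$model_tag, ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> OLS on transformed '", x$outcome, "', n = ", x$n_used,
      " (", x$model_tag, ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy a relative-risk fit
#'
#' One row per model term (intercept dropped): the exponentiated estimate
#' (RR, or OR in `"or"` mode), Wald confidence bounds, p-value, the number
#' of complete cases used and the model tag.
#'
#' @param x An `rr_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `predictor`, `estimate`,
#'   `conf.low`, `conf.high`, `p.value`, `n_used`, `model_tag`, `fallback`.
#' @export
tidy.rr_fit <- function(x, ...) {
  co <- coef(x$model)
  se <- sqrt(diag(x$vcov))
  z <- qnorm(1 - (1 - x$conf_level) / 2)
  keep <- names(co) != "(Intercept)"
  term <- names(co)[keep]
  tibble(
    term = term,
    predictor = match_predictor(term, x$predictors),
    estimate = exp(co[keep]),
    conf.low = exp(co[keep] - z * se[keep]),
    conf.high = exp(co[keep] + z * se[keep]),
    p.value = 2 * pnorm(-abs(co[keep] / se[keep])),
    n_used = x$n_used,
    model_tag = x$model_tag,
    fallback = x$fallback
  )
}

#' @export
glance.rr_fit <- function(x, ...) {
  tibble(
    n_used = x$n_used,
    family = x$family,
    fallback = x$fallback,
    converged = isTRUE(x$model$converged),
    deviance = x$model$deviance,
    aic = x$model$aic
  )
}

#' Tidy a lesion-growth fit
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return A tibble: `term`, `predictor`, `estimate` (slope on the
#'   transformed scale), `conf.low`, `conf.high`, `p.value`, `n_used`,
#'   `model_tag`.
#' @export
tidy.growth_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  ci <- stats::confint(x$model, level = x$conf_level)
  keep <- rownames(sm) != "(Intercept)"
  term <- rownames(sm)[keep]
  tibble(
    term = term,
    predictor = match_predictor(term, x$predictors),
    estimate = sm[keep, "Estimate"],
    conf.low = ci[keep, 1],
    conf.high = ci[keep, 2],
    p.value = sm[keep, "Pr(>|t|)"],
    n_used = x$n_used,
    model_tag = x$model_tag
  )
}

#' @export
glance.growth_fit <- function(x, ...) {
  sm <- summary(x$model)
  tibble(
    n_used = x$n_used,
    r.squared = sm$r.squared,
    adj.r.squared = sm$adj.r.squared,
    sigma = sm$sigma
  )
}

# Map model-matrix terms (e.g. "sexmale") back to the supplied predictor name.
match_predictor <- function(terms, predictors) {
  vapply(terms, function(tm) {
    hit <- predictors[startsWith(tm, predictors)]
    if (length(hit)) hit[which.max(nchar(hit))] else tm
  }, character(1), USE.NAMES = FALSE)
}

#' Univariable screen of candidate predictors
#'
#' Fits one single-predictor model per candidate ([fit_rr()] for a binary
#' outcome, [fit_linear()] for growth) and stacks the tidied rows, tagged
#' `"univariable"`. This is the screening stage of the
#' univariable-to-multivariable model-building convention.
#'
#' @param data Cohort data frame.
#' @param outcome Outcome column (binary for `type = "rr"`; for
#'   `type = "linear"` the response passed to [fit_linear()]).
#' @param predictors Candidate predictor names.
#' @param type `"rr"` or `"linear"`.
#' @param ... Passed to the underlying fitter.
#' @return A tibble of stacked [tidy()] rows.
#' @export
screen_univariable <- function(data, outcome, predictors,
                               type = c("rr", "linear"), ...) {
  type <- match.arg(type)
  purrr::map_dfr(predictors, function(p) {
    fit <- if (type == "rr") {
      fit_rr(data, outcome, p, model_tag = "univariable", ...)
    } else {
      fit_linear(data, p, response = outcome, model_tag = "univariable", ...)
    }
    tidy(fit)
  })
}

#' Select predictors for the multivariable model
#'
#' Keeps the predictors whose univariable p-value falls below `alpha`
#' (for a factor predictor, its smallest term-level p-value), plus any
#' forced adjustments (e.g. sex for the functional-outcome model).
#'
#' @param univariable A tibble of univariable [tidy()] rows (from
#'   [screen_univariable()]).
#' @param alpha Significance threshold; default 0.05.
#' @param force Predictors always included regardless of significance.
#' @return Character vector of selected predictors (order of first
#'   appearance). Warns if the screen selects none.
#' @export
build_multivariable <- function(univariable, alpha = 0.05,
                                force = character()) {
  if (nrow(univariable) == 0L) abort("No univariable results supplied.")
  by_pred <- dplyr::summarise(
    dplyr::group_by(univariable, .data$predictor),
    p_min = min(.data$p.value),
    .groups = "drop")
  sel <- by_pred$predictor[by_pred$p_min < alpha]
  sel <- unique(c(intersect(unique(univariable$predictor), sel), force))
  if (length(sel) == 0L) {
    warn("No univariable predictor reached significance; multivariable model is empty.")
  }
  sel
}

#' Stratified sensitivity analysis by predicted core volume
#'
#' Splits the cohort at a pCore cutoff (upper stratum inclusive:
#' `pcore_ml >= cutoff_ml`) and repeats the univariable screen within each
#' stratum, mirroring the large-core versus small-core sensitivity analysis
#' convention (50 mL matches the inclusion boundary of several endovascular
#' trials).
#'
#' @inheritParams screen_univariable
#' @param cutoff_ml Stratification cutoff in mL; default 50.
#' @return A tibble of per-stratum tidied results with a `stratum` column
#'   (`"pcore_lt_cutoff"` / `"pcore_ge_cutoff"`) and `n_stratum`.
#' @export
stratified_sensitivity <- function(data, outcome, predictors,
                                   cutoff_ml = 50, type = c("rr", "linear"),
                                   ...) {
  type <- match.arg(type)
  if (!"pcore_ml" %in% names(data)) abort("`data` must contain `pcore_ml`.")
  upper <- data$pcore_ml >= cutoff_ml
  if (!any(upper) || all(upper)) {
    abort(sprintf("Both strata must be non-empty at a %.0f mL cutoff.",
                  cutoff_ml))
  }
  strata <- list(pcore_lt_cutoff = data[!upper, , drop = FALSE],
                 pcore_ge_cutoff = data[upper, , drop = FALSE])
  purrr::imap_dfr(strata, function(d, nm) {
    res <- screen_univariable(d, outcome, predictors, type = type, ...)
    dplyr::mutate(res, stratum = nm, n_stratum = nrow(d),
                  cutoff_ml = cutoff_ml)
  })
}

#' Descriptive cohort table with group comparison
#'
#' Summarises every variable (except identifiers and the grouping variable)
#' overall-free, per group: continuous variables are tested for normality
#' (Shapiro-Wilk at 0.05, on up to 5000 sampled values) and reported as mean
#' (SD) when normal, median (IQR) otherwise, with a Wilcoxon rank-sum
#' p-value across the two groups; categorical and logical variables are
#' reported as n (%). Per-variable n is reported whenever values are
#' missing.
#'
#' @param data Cohort data frame.
#' @param group Name of a two-level grouping column; default
#'   `"overestimated"`.
#' @param alpha Normality-test threshold; default 0.05.
#' @return A tibble with one row per variable and group: `variable`,
#'   `group`, `n`, `n_missing`, `summary` (formatted), `distribution`
#'   (`normal`/`non-normal`/`categorical`) and the across-group `p_value`
#'   (Wilcoxon, continuous variables only).
#' @export
describe_cohort <- function(data, group = "overestimated", alpha = 0.05) {
  if (nrow(data) == 0L) abort("Cohort is empty.")
  if (!group %in% names(data)) {
    abort(sprintf("Grouping column '%s' not found.", group))
  }
  g <- data[[group]]
  levs <- sort(unique(g[!is.na(g)]))
  if (length(levs) != 2L) {
    abort(sprintf("Grouping column '%s' must have exactly 2 observed levels.",
                  group))
  }
  if (any(vapply(levs, function(l) sum(g == l, na.rm = TRUE), 0L) == 0L)) {
    abort("Each group must be non-empty.")
  }
  vars <- setdiff(names(data), c(group, "subject_id"))

  purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    is_cont <- is.numeric(x) && length(unique(x[!is.na(x)])) > 2L
    if (is_cont) {
      xs <- x[!is.na(x)]
      sw <- tryCatch(
        shapiro.test(if (length(xs) > 5000) sample(xs, 5000) else xs)$p.value,
        error = function(e) 0)
      normal <- sw >= alpha
      pv <- tryCatch(
        wilcox.test(x[g == levs[1]], x[g == levs[2]], exact = FALSE)$p.value,
        error = function(e) NA_real_)
      purrr::map_dfr(levs, function(l) {
        xi <- x[g == l & !is.na(g)]
        xs <- xi[!is.na(xi)]
        tibble(
          variable = v, group = paste0(group, "=", l),
          n = length(xs), n_missing = sum(is.na(xi)),
          summary = if (normal) {
            sprintf("%.1f (%.1f)", mean(xs), sd(xs))
          } else {
            q <- quantile(xs, c(0.25, 0.5, 0.75))
            sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
          },
          distribution = if (normal) "normal" else "non-normal",
          p_value = pv
        )
      })
    } else {
      purrr::map_dfr(levs, function(l) {
        xi <- x[g == l & !is.na(g)]
        xs <- xi[!is.na(xi)]
        tab <- sort(table(as.character(xs)), decreasing = TRUE)
        lab <- if (is.logical(x)) {
          sprintf("%d (%.1f%%)", sum(xs), 100 * mean(xs))
        } else {
          paste(sprintf("%s: %d (%.1f%%)", names(tab), as.integer(tab),
                        100 * as.integer(tab) / length(xs)),
                collapse = "; ")
        }
        tibble(variable = v, group = paste0(group, "=", l),
               n = length(xs), n_missing = sum(is.na(xi)),
               summary = lab, distribution = "categorical",
               p_value = NA_real_)
      })
    }
  })
}
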