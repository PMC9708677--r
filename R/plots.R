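#' Forest plot of a relative-risk fit
#'
#' @param object An `rr_fit`.
#' @param ... Unused.
#' @return A ggplot: point estimates with confidence bars on a log x scale,
#'   with the null RR = 1 marked.
#' @export
autoplot.rr_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = if (object$family == "or") "Odds ratio (95% CI)" else
        "Relative risk (95% CI)",
      y = NULL,
      title = sprintf("%s model of %s (n = %d)", object$model_tag,
                      object$outcome, object$n_used)) +
    ggplot2::theme_minimal()
}

#' Forest plot of a lesion-growth fit
#'
#' @param object A `growth_fit`.
#' @param ... Unused.
#' @return A ggplot of coefficients on the cube-root-growth scale with the
#'   null effect 0 marked.
#' @export
autoplot.growth_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Coefficient on cube-root growth (95% CI)", y = NULL,
                  title = sprintf("%s growth model (n = %d)",
                                  object$model_tag, object$n_used)) +
    ggplot2::theme_minimal()
}

#' Axial slice of a phantom volume or map
#'
#' @param bundle A `phantom_bundle`.
#' @param which Which grid to show: `"admission"`, `"followup"`, `"rcbf"`
#'   or `"tmax"`.
#' @param slice Axial (third-axis) slice index; defaults to the lesion
#'   centre slice.
#' @return A ggplot raster of the slice with the ischemic-mask outline
#'   overlaid.
#' @export
plot_phantom_slice <- function(bundle,
                               which = c("admission", "followup", "rcbf",
                                         "tmax"),
                               slice = NULL) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  which <- match.arg(which)
  arr <- switch(which,
                admission = bundle$admission_ct$voxels,
                followup = bundle$followup_ct$voxels,
                rcbf = bundle$perfusion$rcbf_pct,
                tmax = bundle$perfusion$tmax_s)
  slice <- slice %||% round(bundle$spec$lesion_center[3])
  d <- tidyr::expand_grid(x = seq_len(dim(arr)[1]), y = seq_len(dim(arr)[2]))
  d$value <- as.vector(arr[, , slice])
  d$lesion <- as.vector(bundle$ischemic_mask[, , slice])
  unit <- switch(which, admission = , followup = "HU", rcbf = "rCBF %",
                 tmax = "Tmax s")
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", name = unit) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s, axial slice %d", which, slice)) +
    ggplot2::theme_void()
  if (any(d$lesion)) {
    p <- p + ggplot2::geom_point(
      data = d[d$lesion, ], colour = "red", size = 0.3, alpha = 0.25)
  }
  p
}

#' Lesion growth versus net water uptake
#'
#' Scatter of cube-root lesion growth against admission NWU with the
#' univariable least-squares line, the study's canonical visualisation of
#' the edema-growth relationship.
#'
#' @param cohort A patient-record tibble with `nwu_pct` and
#'   `lesion_growth_ml`.
#' @return A ggplot.
#' @export
plot_growth_vs_nwu <- function(cohort) {
  d <- cohort[!is.na(cohort$nwu_pct) & !is.na(cohort$lesion_growth_ml), ]
  d$g3 <- cubic_root_transform(d$lesion_growth_ml)
  ggplot2::ggplot(d, ggplot2::aes(.data$nwu_pct, .data$g3)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "firebrick") +
    ggplot2::labs(x = "Net water uptake (%)",
                  y = expression(sqrt(growth ~ (mL), 3))) +
    ggplot2::theme_minimal()
}

#' Predicted overestimation risk across a predictor
#'
#' Plots the fitted risk curve of an `rr_fit` across the observed range of
#' one predictor, holding the remaining predictors at their median (numeric)
#' or most frequent level, with the predicted probability clipped at 1.
#'
#' @param fit An `rr_fit`.
#' @param data The cohort the model was fitted on.
#' @param predictor Predictor to vary; default `"nwu_pct"`.
#' @return A ggplot of predicted probability versus the predictor.
#' @export
plot_risk_curve <- function(fit, data, predictor = "nwu_pct") {
  stopifnot(inherits(fit, "rr_fit"))
  if (!predictor %in% fit$predictors) {
    abort(sprintf("'%s' is not a predictor of this model.", predictor))
  }
  grid <- tibble(!!predictor := seq(min(data[[predictor]], na.rm = TRUE),
                                    max(data[[predictor]], na.rm = TRUE),
                                    length.out = 200))
  for (p in setdiff(fit$predictors, predictor)) {
    v <- data[[p]]
    grid[[p]] <- if (is.numeric(v)) {
      median(v, na.rm = TRUE)
    } else {
      names(sort(table(v), decreasing = TRUE))[1]
    }
  }
  grid$risk <- pmin(predict(fit$model, newdata = grid, type = "response"), 1)
  ggplot2::ggplot(grid, ggplot2::aes(.data[[predictor]], .data$risk)) +
    ggplot2::geom_line(colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = predictor,
                  y = sprintf("Predicted P(%s)", fit$outcome)) +
    ggplot2::ylim(0, NA) +
    ggplot2::theme_minimal()
}
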