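#' Perfusion map container
#'
#' Holds the CT-perfusion parameter maps from which threshold volumes are
#' derived: relative cerebral blood flow (rCBF, % of contralateral normal)
#' and time-to-maximum (Tmax, seconds), with a brain mask restricting all
#' thresholding to intracranial tissue.
#'
#' @param rcbf_pct 3-D numeric array, rCBF as a percentage (>= 0).
#' @param tmax_s 3-D numeric array, Tmax in seconds (>= 0 inside the brain).
#' @param brain_mask Logical 3-D array of brain voxels.
#' @param spacing_mm Voxel size per axis in mm (length 1 or 3).
#'
#' @return An object of class `perfusion_maps`.
#' @export
perfusion_maps <- function(rcbf_pct, tmax_s, brain_mask, spacing_mm) {
  if (!identical(dim(rcbf_pct), dim(tmax_s)) ||
      !identical(dim(rcbf_pct), dim(brain_mask))) {
    abort("rCBF, Tmax and brain mask grids must share one shape.")
  }
  brain_mask <- array(as.logical(brain_mask), dim(brain_mask))
  if (any(rcbf_pct[brain_mask] < 0, na.rm = TRUE)) {
    abort("rCBF must be non-negative inside the brain mask.")
  }
  if (any(tmax_s[brain_mask] < 0, na.rm = TRUE)) {
    abort("Tmax must be non-negative inside the brain mask.")
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (any(spacing_mm <= 0)) abort("`spacing_mm` must be strictly positive.")
  structure(
    list(rcbf_pct = rcbf_pct, tmax_s = tmax_s, brain_mask = brain_mask,
         spacing_mm = spacing_mm),
    class = "perfusion_maps"
  )
}

#' Volume of a binary mask in millilitres
#'
#' @param mask Logical (or 0/1) array.
#' @param spacing_mm Voxel size per axis in mm (length 1 or 3).
#'
#' @return Voxel count times voxel volume (mm^3) / 1000, in mL. An empty mask
#'   has volume 0.
#' @export
#' @examples
#' volume_ml(array(TRUE, c(10, 10, 10)), 1)  # 1 mL
volume_ml <- function(mask, spacing_mm) {
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    abort("`spacing_mm` must be strictly positive.")
  }
  sum(as.logical(mask), na.rm = TRUE) * prod(spacing_mm) / 1000
}

#' Predicted ischemic core volume from the rCBF threshold
#'
#' The predicted core (pCore) is the volume of brain tissue whose relative
#' cerebral blood flow is at or below `rcbf_threshold` percent of the
#' contralateral normal value. The boundary is inclusive (rCBF <= threshold).
#'
#' @param maps A [perfusion_maps()].
#' @param rcbf_threshold Threshold in percent, in (0, 100]; default 20.
#'
#' @return pCore volume in mL.
#' @export
compute_pcore <- function(maps, rcbf_threshold = 20) {
  stopifnot(inherits(maps, "perfusion_maps"))
  if (!is.numeric(rcbf_threshold) || rcbf_threshold <= 0 ||
      rcbf_threshold > 100) {
    abort("`rcbf_threshold` must lie in (0, 100] percent.")
  }
  core <- maps$brain_mask & (maps$rcbf_pct <= rcbf_threshold)
  volume_ml(core, maps$spacing_mm)
}

#' Hypoperfusion and penumbral (mismatch) volumes from the Tmax threshold
#'
#' Hypoperfusion is the volume of brain tissue with Tmax at or above
#' `tmax_threshold` seconds (inclusive by default; the boundary convention is
#' configurable via `inclusive`). The penumbra (mismatch) is hypoperfusion
#' minus the predicted core; if the core extends outside the Tmax lesion the
#' difference can be negative, in which case it is floored at 0 with a
#' warning.
#'
#' @param maps A [perfusion_maps()].
#' @param pcore_ml Predicted core volume in mL (>= 0).
#' @param tmax_threshold Threshold in seconds; default 6.
#' @param inclusive Count voxels exactly at the threshold? Default `TRUE`.
#'
#' @return A one-row tibble: `hypoperfusion_ml`, `penumbra_ml`.
#' @export
compute_penumbra <- function(maps, pcore_ml, tmax_threshold = 6,
                             inclusive = TRUE) {
  stopifnot(inherits(maps, "perfusion_maps"))
  if (!is.numeric(pcore_ml) || pcore_ml < 0) {
    abort("`pcore_ml` must be non-negative.")
  }
  hypo <- if (inclusive) {
    maps$brain_mask & (maps$tmax_s >= tmax_threshold)
  } else {
    maps$brain_mask & (maps$tmax_s > tmax_threshold)
  }
  hypo_ml <- volume_ml(hypo, maps$spacing_mm)
  pen <- hypo_ml - pcore_ml
  if (pen < 0) {
    warn(sprintf(
      "Predicted core (%.1f mL) exceeds the Tmax lesion (%.1f mL); penumbra floored at 0.",
      pcore_ml, hypo_ml))
    pen <- 0
  }
  tibble(hypoperfusion_ml = hypo_ml, penumbra_ml = pen)
}

#' Lesion growth between admission and follow-up
#'
#' Growth = final infarct volume (FIV) minus predicted core volume, in mL.
#' Negative growth means the admission perfusion core was larger than the
#' final infarct.
#'
#' @param fiv_ml Final infarct volume in mL (>= 0).
#' @param pcore_ml Predicted core volume in mL (>= 0).
#'
#' @return Signed growth in mL. Vectorised.
#' @export
#' @examples
#' lesion_growth(50, 30)    # 20
#' lesion_growth(10, 34.2)  # -24.2
lesion_growth <- function(fiv_ml, pcore_ml) {
  if (any(fiv_ml < 0, na.rm = TRUE) || any(pcore_ml < 0, na.rm = TRUE)) {
    abort("Volumes must be non-negative.")
  }
  fiv_ml - pcore_ml
}

#' Classify CT-perfusion core overestimation
#'
#' A predicted core is scored as overestimated ("ghost infarct core") when
#' lesion growth is negative by more than 10 mL, i.e. strictly below the
#' threshold: growth of exactly -10 mL is not overestimation. The 10 mL
#' margin absorbs segmentation error.
#'
#' @param growth_ml Lesion growth in mL (finite). Vectorised.
#' @param threshold_ml Overestimation threshold, default -10 mL.
#'
#' @return Logical: `TRUE` iff `growth_ml < threshold_ml`.
#' @export
#' @examples
#' classify_overestimation(c(-10, -10.1, 18.4))  # FALSE TRUE FALSE
classify_overestimation <- function(growth_ml, threshold_ml = -10) {
  if (any(!is.finite(growth_ml))) abort("`growth_ml` must be finite.")
  growth_ml < threshold_ml
}

#' Signed cube root
#'
#' Lesion growth is heavily right-skewed and can be negative; the signed cube
#' root `sign(x) * |x|^(1/3)` is the standard odd monotone transform that
#' symmetrises it while preserving sign and order.
#'
#' @param x Numeric vector.
#' @return `sign(x) * abs(x)^(1/3)`.
#' @export
#' @examples
#' cubic_root_transform(c(8, -8, 0))  # 2 -2 0
cubic_root_transform <- function(x) {
  sign(x) * abs(x)^(1 / 3)
}
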