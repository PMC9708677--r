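#' CT volume container
#'
#' Wraps a 3-D grid of Hounsfield-unit (HU) values together with its voxel
#' spacing and the location of the midsagittal plane, which defines left-right
#' symmetry for contralateral mirror-ROI densitometry.
#'
#' The midsagittal plane is a voxel plane: grid index `midline_index` along
#' `midline_axis`. Mirroring maps index `i` to `2 * midline_index - i`, so a
#' head centred on an odd-extent axis mirrors exactly. An off-centre head is
#' accommodated by setting `midline_index` away from the grid centre.
#'
#' @param voxels 3-D numeric array of HU values.
#' @param spacing_mm Numeric vector of length 3, voxel size per axis in mm.
#' @param midline_axis Integer in 1:3, the left-right grid axis.
#' @param midline_index Grid index of the midsagittal voxel plane along
#'   `midline_axis`. Defaults to the central plane `(dim + 1) / 2` (rounded).
#'
#' @return An object of class `ct_volume`.
#' @export
#' @examples
#' ct <- ct_volume(array(35, c(11, 11, 5)), spacing_mm = c(1, 1, 5))
#' dim(ct$voxels)
ct_volume <- function(voxels, spacing_mm, midline_axis = 1L,
                      midline_index = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    abort("`voxels` must be a 3-D array of HU values.")
  }
  if (any(dim(voxels) < 1L)) abort("`voxels` must be non-empty.")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    abort("`spacing_mm` must be 3 strictly positive voxel sizes (mm).")
  }
  midline_axis <- as.integer(midline_axis)
  if (!midline_axis %in% 1:3) abort("`midline_axis` must be 1, 2 or 3.")
  n_mid <- dim(voxels)[midline_axis]
  midline_index <- as.integer(midline_index %||% ((n_mid + 1L) %/% 2L))
  if (midline_index < 1L || midline_index > n_mid) {
    abort("`midline_index` lies outside the grid.")
  }
  structure(
    list(voxels = voxels, spacing_mm = spacing_mm,
         midline_axis = midline_axis, midline_index = midline_index),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing_mm, 3), collapse = " x "),
      " mm, midline axis ", x$midline_axis,
      " @ index ", x$midline_index, "\n", sep = "")
  invisible(x)
}

#' Reflect a binary mask across the midsagittal plane
#'
#' Produces the contralateral mirror of an ischemic-lesion mask: each voxel at
#' index `i` along the midline axis maps to `2 * index - i`. This is the
#' deterministic analog of manually mirroring a region of interest onto the
#' non-affected hemisphere; no registration is performed, so it assumes the
#' head is (approximately) symmetric about the configured plane.
#'
#' @param mask Logical (or 0/1) 3-D array; the ischemic-lesion mask.
#' @param midline_axis Integer in 1:3, the left-right grid axis.
#' @param midline_index Grid index of the midsagittal voxel plane.
#'
#' @return Logical array of the same shape: the reflected mask. Voxel count is
#'   preserved. Errors if the mask is empty, falls partly outside the grid
#'   after reflection, or intersects its own reflection (a lesion crossing the
#'   midline cannot be mirrored onto unaffected tissue).
#' @export
#' @examples
#' m <- array(FALSE, c(9, 5, 3)); m[2, 3, 2] <- TRUE
#' which(mirror_roi(m, 1, 5))  # voxel at index 8 = 2*5 - 2
mirror_roi <- function(mask, midline_axis = 1L, midline_index = NULL) {
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    abort("`mask` must be a 3-D array.")
  }
  mask <- array(as.logical(mask), dim(mask))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("`mask` is empty; nothing to mirror.")
  midline_axis <- as.integer(midline_axis)
  n_mid <- dim(mask)[midline_axis]
  midline_index <- as.integer(midline_index %||% ((n_mid + 1L) %/% 2L))
  ref <- idx
  ref[, midline_axis] <- 2L * midline_index - idx[, midline_axis]
  if (any(ref[, midline_axis] < 1L) || any(ref[, midline_axis] > n_mid)) {
    abort("Reflected mask falls outside the grid; check the midline plane.")
  }
  out <- array(FALSE, dim(mask))
  out[ref] <- TRUE
  if (any(out & mask)) {
    abort(paste0("Mask intersects its own reflection: the lesion crosses the ",
                 "midsagittal plane, so a contralateral mirror ROI would ",
                 "overlap ischemic tissue."))
  }
  out
}

#' Pair an ischemic mask with its contralateral mirror
#'
#' Builds the two-ROI set used for net water uptake densitometry: the ischemic
#' lesion mask and its exact reflection across the CT volume's midsagittal
#' plane.
#'
#' @param ct A [ct_volume()].
#' @param ischemic_mask Logical 3-D array matching the volume grid.
#'
#' @return An object of class `roi_set` with elements `ischemic_mask` and
#'   `mirror_mask` (disjoint, equal voxel counts).
#' @export
roi_set <- function(ct, ischemic_mask) {
  stopifnot(inherits(ct, "ct_volume"))
  if (!identical(dim(ischemic_mask), dim(ct$voxels))) {
    abort("`ischemic_mask` shape does not match the CT grid.")
  }
  ischemic_mask <- array(as.logical(ischemic_mask), dim(ischemic_mask))
  mirror <- mirror_roi(ischemic_mask, ct$midline_axis, ct$midline_index)
  structure(
    list(ischemic_mask = ischemic_mask, mirror_mask = mirror),
    class = "roi_set"
  )
}

#' Window HU samples to the parenchymal density range
#'
#' Retains values with `lo <= v <= hi` (both bounds inclusive), in their
#' original order. The default 20-80 HU window excludes voxels whose density
#' corresponds to cerebrospinal fluid (low HU) or calcification (high HU) so
#' that ROI means reflect brain parenchyma only.
#'
#' @param values Numeric vector of HU samples.
#' @param lo,hi Inclusive window bounds in HU.
#'
#' @return The surviving values (possibly empty; downstream consumers must
#'   not silently average an empty vector).
#' @export
#' @examples
#' filter_hu(c(15, 30, 85))  # 30
#' filter_hu(c(20, 80))      # both kept: bounds are inclusive
filter_hu <- function(values, lo = 20, hi = 80) {
  if (!is.numeric(values)) abort("`values` must be numeric HU samples.")
  if (any(!is.finite(values))) abort("`values` must be finite.")
  if (!is.finite(lo) || !is.finite(hi) || lo > hi) {
    abort("HU window must satisfy lo <= hi.")
  }
  values[values >= lo & values <= hi]
}

#' Percent net water uptake from mirror-ROI densitometry
#'
#' Computes %NWU = (1 - D_ischemic / D_normal) * 100 where D_ischemic and
#' D_normal are the densities of the HU-windowed ischemic ROI and its
#' contralateral mirror. Density is the arithmetic mean of surviving voxels by
#' default; `statistic = "median"` is available since the choice of ROI
#' statistic is a convention, not a law.
#'
#' Negative values are returned as computed (possible with noise when the
#' lesion is nearly isodense); clipping at zero would bias recovery studies.
#'
#' @param ct A [ct_volume()].
#' @param rois An [roi_set()] (or a logical lesion mask, from which the ROI
#'   set is built).
#' @param hu_window Inclusive HU window, default `c(20, 80)`.
#' @param statistic ROI density statistic, `"mean"` (default) or `"median"`.
#'
#' @return A one-row tibble: `nwu_pct`, `d_ischemic`, `d_normal`,
#'   `n_ischemic`, `n_normal`, `statistic`.
#' @export
#' @examples
#' vox <- array(35, c(9, 5, 3))
#' vox[2:3, 2:3, 2] <- 31.5
#' ct <- ct_volume(vox, c(2, 2, 2))
#' m <- array(FALSE, dim(vox)); m[2:3, 2:3, 2] <- TRUE
#' compute_nwu(ct, m)  # 10% uptake
compute_nwu <- function(ct, rois, hu_window = c(20, 80),
                        statistic = c("mean", "median")) {
  stopifnot(inherits(ct, "ct_volume"))
  statistic <- match.arg(statistic)
  if (!inherits(rois, "roi_set")) rois <- roi_set(ct, rois)
  if (!identical(dim(rois$ischemic_mask), dim(ct$voxels))) {
    abort("ROI set shape does not match the CT grid.")
  }
  fn <- if (statistic == "mean") mean else median
  isch <- filter_hu(ct$voxels[rois$ischemic_mask], hu_window[1], hu_window[2])
  norm <- filter_hu(ct$voxels[rois$mirror_mask], hu_window[1], hu_window[2])
  if (length(isch) == 0L) {
    abort("No ischemic-ROI voxel survives the HU window; cannot compute NWU.")
  }
  if (length(norm) == 0L) {
    abort("No mirror-ROI voxel survives the HU window; cannot compute NWU.")
  }
  d_isch <- fn(isch)
  d_norm <- fn(norm)
  # post-filter densities are >= hu_window[1] > 0, so the ratio is defined
  stopifnot(d_norm > 0)
  tibble(
    nwu_pct = (1 - d_isch / d_norm) * 100,
    d_ischemic = d_isch,
    d_normal = d_norm,
    n_ischemic = length(isch),
    n_normal = length(norm),
    statistic = statistic
  )
}
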