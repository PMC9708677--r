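#' Specification of a synthetic head-CT phantom
#'
#' Defines the geometry, densities and noise of a digital phantom used to
#' validate the densitometry and volumetric pipeline against known ground
#' truth. The phantom is an ellipsoidal "brain" of uniform parenchymal
#' density in an axial grid whose midsagittal plane is a voxel plane (the
#' left-right axis extent must be odd), with:
#'
#' * an ellipsoidal ischemic lesion confined to one hemisphere whose density
#'   deficit encodes the ground-truth water uptake:
#'   `lesion HU = tissue_hu * (1 - true_nwu_pct / 100)`;
#' * cerebrospinal-fluid (CSF) and calcification inclusions placed inside the
#'   lesion ROI to exercise the 20-80 HU parenchymal window, plus symmetric
#'   paramedian CSF "ventricles";
#' * an inner core subregion where rCBF is far below the 20% threshold and a
#'   surrounding hypoperfused region where Tmax exceeds 6 s;
#' * a follow-up volume with an infarct (FIV) region of configurable size, so
#'   lesion growth and core overestimation have known truth;
#' * optional additive Gaussian HU noise.
#'
#' No skull or beam-hardening is modelled: the brain window is assumed
#' pre-stripped, which keeps left-right mirroring exact.
#'
#' @param grid_shape Integer vector of length 3, voxels per axis. The first
#'   (left-right) extent must be odd so the midline is a voxel plane.
#' @param voxel_size_mm Isotropic voxel spacing in mm.
#' @param tissue_hu Mean normal parenchymal density (HU), in (20, 80).
#' @param csf_hu Ventricular/CSF density (HU), below 20.
#' @param calcification_hu Calcification density (HU), above 80.
#' @param lesion_center Voxel coordinates (length 3) of the lesion centre.
#'   Default places it in the low-index hemisphere of the default grid.
#' @param lesion_radii_mm Ellipsoid semi-axes of the lesion in mm.
#' @param core_radii_mm Semi-axes of the low-rCBF core subregion (centred on
#'   the lesion).
#' @param hypo_radii_mm Semi-axes of the prolonged-Tmax hypoperfused region.
#' @param fiv_radii_mm Semi-axes of the follow-up infarct region.
#' @param true_nwu_pct Ground-truth percent net water uptake, in \[0, 100).
#' @param followup_nwu_pct Water uptake applied to the follow-up infarct
#'   region (visual only; follow-up densitometry is not part of the method).
#' @param noise_sd_hu SD of additive Gaussian HU noise (0 = noise-free).
#' @param seed RNG seed for the noise draw (`NULL` = leave RNG state alone).
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(61L, 73L, 61L),
                         voxel_size_mm = 2,
                         tissue_hu = 35,
                         csf_hu = 10,
                         calcification_hu = 200,
                         lesion_center = NULL,
                         lesion_radii_mm = c(16, 20, 16),
                         core_radii_mm = c(11, 14, 11),
                         hypo_radii_mm = c(21, 26, 21),
                         fiv_radii_mm = c(18, 22, 18),
                         true_nwu_pct = 7.2,
                         followup_nwu_pct = 22,
                         noise_sd_hu = 1.5,
                         seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 9L)) {
    abort("`grid_shape` must be 3 extents of at least 9 voxels.")
  }
  if (grid_shape[1] %% 2L == 0L) {
    abort("Left-right extent (`grid_shape[1]`) must be odd so the midsagittal plane is a voxel plane.")
  }
  if (!(tissue_hu > 20 && tissue_hu < 80)) {
    abort("`tissue_hu` must lie strictly inside the 20-80 HU window.")
  }
  if (!(csf_hu < 20)) abort("`csf_hu` must be below 20 HU.")
  if (!(calcification_hu > 80)) abort("`calcification_hu` must exceed 80 HU.")
  if (!(true_nwu_pct >= 0 && true_nwu_pct < 100)) {
    abort("`true_nwu_pct` must lie in [0, 100).")
  }
  if (noise_sd_hu < 0) abort("`noise_sd_hu` must be non-negative.")
  if (voxel_size_mm <= 0) abort("`voxel_size_mm` must be positive.")
  lesion_center <- lesion_center %||%
    c(round(grid_shape[1] * 0.28), (grid_shape[2] + 1) %/% 2,
      (grid_shape[3] + 1) %/% 2)
  structure(
    list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
         tissue_hu = tissue_hu, csf_hu = csf_hu,
         calcification_hu = calcification_hu,
         lesion_center = as.numeric(lesion_center),
         lesion_radii_mm = as.numeric(lesion_radii_mm),
         core_radii_mm = as.numeric(core_radii_mm),
         hypo_radii_mm = as.numeric(hypo_radii_mm),
         fiv_radii_mm = as.numeric(fiv_radii_mm),
         true_nwu_pct = true_nwu_pct,
         followup_nwu_pct = followup_nwu_pct,
         noise_sd_hu = noise_sd_hu, seed = seed),
    class = "phantom_spec"
  )
}

#' Ellipsoid radius (mm) of a sphere with a given volume
#'
#' Convenience for designing phantom regions with a target volume:
#' `r = (3 V / 4 pi)^(1/3)` with V in mm^3.
#'
#' @param volume_ml Target volume in mL.
#' @return Radius in mm.
#' @export
sphere_radius_mm <- function(volume_ml) {
  (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
}

# Logical mask of an ellipsoid given centre (voxel coords) and semi-axes (mm).
ellipsoid_mask <- function(grid_shape, center_vox, radii_mm, voxel_size_mm) {
  r_vox <- radii_mm / voxel_size_mm
  dx <- (seq_len(grid_shape[1]) - center_vox[1]) / r_vox[1]
  dy <- (seq_len(grid_shape[2]) - center_vox[2]) / r_vox[2]
  dz <- (seq_len(grid_shape[3]) - center_vox[3]) / r_vox[3]
  d2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  array(d2 <= 1, grid_shape)
}

#' Generate a synthetic head-CT phantom with known ground truth
#'
#' Builds the full image set a measurement pipeline consumes — admission and
#' follow-up CT volumes, rCBF and Tmax perfusion maps, ischemic and
#' follow-up-infarct masks — from a [phantom_spec()], together with a `truth`
#' record of every quantity the pipeline should recover: the lesion mean HU
#' (`tissue_hu * (1 - true_nwu_pct / 100)`), the true NWU, and the true
#' pCore, hypoperfusion, penumbra, FIV, lesion growth and overestimation
#' flag (mask voxel counts times voxel volume).
#'
#' Noise-free phantoms are exactly left-right symmetric outside the lesion,
#' so mirror-ROI densitometry is exact. Gaussian noise (if any) is added to
#' every voxel after the deterministic construction; the expected ROI means
#' are unchanged.
#'
#' @param spec A [phantom_spec()].
#'
#' @return An object of class `phantom_bundle`: `admission_ct`,
#'   `followup_ct` ([ct_volume()]s), `perfusion` ([perfusion_maps()]),
#'   logical masks `ischemic_mask`, `fiv_mask`, `core_mask`, `hypo_mask`,
#'   `brain_mask`, and lists `truth` and `spec`.
#' @export
#' @examples
#' b <- generate_phantom(phantom_spec(noise_sd_hu = 0))
#' b$truth$lesion_mean_hu  # 35 * (1 - 7.2/100)
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  vs <- spec$voxel_size_mm
  mid <- (gs[1] + 1L) %/% 2L
  center <- c(mid, (gs[2] + 1) / 2, (gs[3] + 1) / 2)

  brain <- ellipsoid_mask(gs, center, (gs * vs) * 0.45, vs)
  lesion <- ellipsoid_mask(gs, spec$lesion_center, spec$lesion_radii_mm, vs)
  if (!any(lesion)) abort("Lesion ellipsoid contains no voxel; enlarge it.")
  if (any(lesion & !brain)) {
    abort("Lesion extends outside the brain; it must fit in one hemisphere.")
  }
  # also rejects a lesion touching/crossing the midsagittal plane
  lesion_mirror <- mirror_roi(lesion, 1L, mid)

  core <- ellipsoid_mask(gs, spec$lesion_center, spec$core_radii_mm, vs) & brain
  hypo <- ellipsoid_mask(gs, spec$lesion_center, spec$hypo_radii_mm, vs) & brain
  fiv <- ellipsoid_mask(gs, spec$lesion_center, spec$fiv_radii_mm, vs) & brain

  # confounder inclusions inside the lesion ROI: a CSF pocket and a speck of
  # calcification, sized relative to the lesion so they stay interior
  csf_in <- ellipsoid_mask(
    gs, spec$lesion_center + c(0, -spec$lesion_radii_mm[2] / (2.5 * vs), 0),
    spec$lesion_radii_mm / 4, vs) & lesion
  calc_in <- ellipsoid_mask(
    gs, spec$lesion_center + c(0, spec$lesion_radii_mm[2] / (2.5 * vs), 0),
    spec$lesion_radii_mm / 6, vs) & lesion

  # symmetric paramedian ventricles (clipped symmetrically away from the
  # lesion and its mirror so noise-free symmetry outside the lesion is exact)
  vent_off <- 4
  vent_r <- c(3, 12, 8)
  vent <- (ellipsoid_mask(gs, center + c(-vent_off, 0, 0), vent_r, vs) |
             ellipsoid_mask(gs, center + c(vent_off, 0, 0), vent_r, vs)) &
    brain & !lesion & !lesion_mirror

  lesion_hu <- spec$tissue_hu * (1 - spec$true_nwu_pct / 100)
  adm <- array(-1000, gs)
  adm[brain] <- spec$tissue_hu
  adm[lesion] <- lesion_hu
  adm[vent] <- spec$csf_hu
  adm[csf_in] <- spec$csf_hu
  adm[calc_in] <- spec$calcification_hu

  fu <- array(-1000, gs)
  fu[brain] <- spec$tissue_hu
  fu[fiv] <- spec$tissue_hu * (1 - spec$followup_nwu_pct / 100)
  fu[vent] <- spec$csf_hu

  rcbf <- array(0, gs)
  rcbf[brain] <- 100
  rcbf[core] <- 10
  tmax <- array(0, gs)
  tmax[hypo] <- 8

  if (spec$noise_sd_hu > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    adm <- adm + array(rnorm(length(adm), 0, spec$noise_sd_hu), gs)
    fu <- fu + array(rnorm(length(fu), 0, spec$noise_sd_hu), gs)
  }

  vol <- function(m) volume_ml(m, vs)
  truth <- list(
    tissue_hu = spec$tissue_hu,
    true_nwu_pct = spec$true_nwu_pct,
    lesion_mean_hu = lesion_hu,
    pcore_ml = vol(core),
    hypoperfusion_ml = vol(hypo),
    penumbra_ml = vol(hypo) - vol(core),
    fiv_ml = vol(fiv),
    lesion_growth_ml = vol(fiv) - vol(core),
    overestimated = (vol(fiv) - vol(core)) < -10,
    lesion_ml = vol(lesion)
  )

  structure(
    list(
      admission_ct = ct_volume(adm, rep(vs, 3), 1L, mid),
      followup_ct = ct_volume(fu, rep(vs, 3), 1L, mid),
      perfusion = perfusion_maps(rcbf, tmax, brain, rep(vs, 3)),
      ischemic_mask = lesion,
      fiv_mask = fiv,
      core_mask = core,
      hypo_mask = hypo,
      brain_mask = brain,
      truth = truth,
      spec = spec
    ),
    class = "phantom_bundle"
  )
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat("<phantom_bundle> grid ", paste(dim(x$admission_ct$voxels), collapse = " x "),
      ", voxel ", x$spec$voxel_size_mm, " mm\n",
      "  true NWU ", x$truth$true_nwu_pct, "% | pCore ",
      round(x$truth$pcore_ml, 1), " mL | FIV ", round(x$truth$fiv_ml, 1),
      " mL | growth ", round(x$truth$lesion_growth_ml, 1), " mL\n", sep = "")
  invisible(x)
}

#' Write a phantom bundle to disk as NIfTI volumes plus a truth sidecar
#'
#' Volumes and maps are written as NIfTI-1 files (`admission.nii.gz`,
#' `followup.nii.gz`, `rcbf.nii.gz`, `tmax.nii.gz`), masks as 0/1 NIfTI
#' volumes, and the ground-truth record plus spec as `truth.json`.
#'
#' @param bundle A [generate_phantom()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(bundle, dir) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- bundle$admission_ct$spacing_mm
  wr <- function(arr, name) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- vs
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")))
  }
  wr(bundle$admission_ct$voxels, "admission")
  wr(bundle$followup_ct$voxels, "followup")
  wr(bundle$perfusion$rcbf_pct, "rcbf")
  wr(bundle$perfusion$tmax_s, "tmax")
  for (m in c("ischemic_mask", "fiv_mask", "core_mask", "hypo_mask",
              "brain_mask")) {
    wr(array(as.integer(bundle[[m]]), dim(bundle[[m]])), m)
  }
  sidecar <- list(
    truth = bundle$truth,
    spec = unclass(bundle$spec),
    midline_axis = bundle$admission_ct$midline_axis,
    midline_index = bundle$admission_ct$midline_index
  )
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a phantom bundle written by [write_phantom()]
#'
#' @param dir Directory containing the NIfTI volumes and `truth.json`.
#' @return A `phantom_bundle`.
#' @export
read_phantom <- function(dir) {
  side_path <- file.path(dir, "truth.json")
  if (!file.exists(side_path)) {
    abort(sprintf("No truth.json sidecar in '%s'.", dir))
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  rd <- function(name) {
    img <- RNifti::readNifti(file.path(dir, paste0(name, ".nii.gz")))
    array(as.numeric(img), dim(img))
  }
  adm <- rd("admission")
  vs <- RNifti::pixdim(RNifti::readNifti(file.path(dir, "admission.nii.gz")))[1:3]
  masks <- lapply(
    setNames(nm = c("ischemic_mask", "fiv_mask", "core_mask", "hypo_mask",
                    "brain_mask")),
    function(m) {
      a <- rd(m)
      array(a > 0.5, dim(a))
    })
  spec <- side$spec
  spec$seed <- spec$seed %||% NULL
  spec <- do.call(phantom_spec, spec[!vapply(spec, is.null, logical(1))])
  structure(
    c(list(
      admission_ct = ct_volume(adm, vs, side$midline_axis, side$midline_index),
      followup_ct = ct_volume(rd("followup"), vs, side$midline_axis,
                              side$midline_index),
      perfusion = perfusion_maps(rd("rcbf"), rd("tmax"), masks$brain_mask, vs)
    ),
    masks,
    list(truth = as.list(side$truth), spec = spec)),
    class = "phantom_bundle"
  )
}
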