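test_that("phantom_spec enforces its invariants", {
  expect_error(phantom_spec(true_nwu_pct = 100), "0, 100")
  expect_error(phantom_spec(true_nwu_pct = -1), "0, 100")
  expect_error(phantom_spec(tissue_hu = 15), "20-80")
  expect_error(phantom_spec(csf_hu = 25), "below 20")
  expect_error(phantom_spec(calcification_hu = 60), "exceed 80")
  expect_error(phantom_spec(grid_shape = c(60, 73, 61)), "odd")
  expect_error(phantom_spec(noise_sd_hu = -1), "non-negative")
})

test_that("a lesion touching or crossing the midline is rejected", {
  # centre the lesion on the midsagittal plane
  bad <- phantom_spec(lesion_center = c(31, 37, 31), noise_sd_hu = 0)
  expect_error(generate_phantom(bad), "midsagittal|reflection")
  # push the lesion outside the brain
  out <- phantom_spec(lesion_center = c(3, 5, 5), noise_sd_hu = 0)
  expect_error(generate_phantom(out), "outside the brain")
})

test_that("noise-free phantom densities are exact", {
  spec <- phantom_spec(tissue_hu = 35, true_nwu_pct = 10, noise_sd_hu = 0)
  b <- generate_phantom(spec)
  expect_equal(b$truth$lesion_mean_hu, 31.5)  # 35 * 0.9

  # windowed lesion mean equals the analytic density exactly: CSF and
  # calcification inclusions fall outside the 20-80 HU window
  lesion_vals <- filter_hu(b$admission_ct$voxels[b$ischemic_mask])
  expect_equal(mean(lesion_vals), 31.5)
  expect_lt(length(lesion_vals), sum(b$ischemic_mask))  # some were excluded

  # the windowed mean equals the mean over pure lesion-tissue voxels
  tissue_vox <- b$admission_ct$voxels[b$ischemic_mask]
  pure <- tissue_vox[tissue_vox != spec$csf_hu &
                       tissue_vox != spec$calcification_hu]
  expect_equal(mean(lesion_vals), mean(pure))

  # mirror ROI sits in unaffected tissue at exactly tissue_hu
  rs <- roi_set(b$admission_ct, b$ischemic_mask)
  expect_equal(mean(b$admission_ct$voxels[rs$mirror_mask]), 35)

  # end-to-end NWU is exact
  expect_equal(compute_nwu(b$admission_ct, b$ischemic_mask)$nwu_pct, 10)
})

test_that("zero uptake yields zero NWU", {
  b <- generate_phantom(phantom_spec(true_nwu_pct = 0, noise_sd_hu = 0))
  expect_equal(compute_nwu(b$admission_ct, b$ischemic_mask)$nwu_pct, 0)
})

test_that("noise-free phantoms are left-right symmetric outside the lesion", {
  b <- generate_phantom(phantom_spec(noise_sd_hu = 0))
  vox <- b$admission_ct$voxels
  flipped <- vox[rev(seq_len(dim(vox)[1])), , ]
  asym <- b$ischemic_mask |
    mirror_roi(b$ischemic_mask, 1, b$admission_ct$midline_index)
  expect_equal(vox[!asym], flipped[!asym])
})

test_that("perfusion maps respect the core and hypoperfusion thresholds", {
  b <- generate_phantom(phantom_spec(noise_sd_hu = 0))
  expect_true(all(b$perfusion$rcbf_pct[b$core_mask] <= 20))
  expect_true(all(b$perfusion$tmax_s[b$hypo_mask] >= 6))
  expect_true(all(b$perfusion$rcbf_pct[b$brain_mask & !b$core_mask] > 20))
})

test_that("truth volumes equal mask voxel count times voxel volume", {
  b <- generate_phantom(phantom_spec(noise_sd_hu = 0))
  vv <- prod(b$admission_ct$spacing_mm) / 1000
  expect_equal(b$truth$pcore_ml, sum(b$core_mask) * vv)
  expect_equal(b$truth$fiv_ml, sum(b$fiv_mask) * vv)
  expect_equal(b$truth$hypoperfusion_ml, sum(b$hypo_mask) * vv)
  expect_equal(b$truth$lesion_growth_ml, b$truth$fiv_ml - b$truth$pcore_ml)
})

test_that("a core designed for a target volume lands close to it", {
  # 34.2 mL target: voxelised ellipsoid volume within 5% of the design
  r <- sphere_radius_mm(34.2)
  b <- generate_phantom(phantom_spec(core_radii_mm = rep(r, 3),
                                     hypo_radii_mm = rep(r + 8, 3),
                                     lesion_radii_mm = rep(r + 2, 3),
                                     lesion_center = c(15, 37, 31),
                                     noise_sd_hu = 0))
  expect_lt(abs(b$truth$pcore_ml - 34.2) / 34.2, 0.05)
  # and the pipeline recovers the voxelised truth exactly
  expect_equal(compute_pcore(b$perfusion), b$truth$pcore_ml)
})

test_that("phantom generation is deterministic under a fixed seed", {
  s <- phantom_spec(noise_sd_hu = 1.5, seed = 99)
  b1 <- generate_phantom(s)
  b2 <- generate_phantom(s)
  expect_identical(b1$admission_ct$voxels, b2$admission_ct$voxels)
  expect_identical(b1$followup_ct$voxels, b2$followup_ct$voxels)
})

test_that("noisy phantoms keep the expected ROI densities", {
  # noise averages out over the ROI: estimate stays close to truth
  errs <- vapply(1:15, function(s) {
    b <- generate_phantom(phantom_spec(true_nwu_pct = 7.2, noise_sd_hu = 1.5,
                                       seed = s))
    compute_nwu(b$admission_ct, b$ischemic_mask)$nwu_pct - 7.2
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.5)
})

test_that("phantom bundles round-trip through NIfTI plus JSON sidecar", {
  dir <- withr::local_tempdir()
  b <- generate_phantom(phantom_spec(noise_sd_hu = 0))
  write_phantom(b, dir)
  expect_true(file.exists(file.path(dir, "admission.nii.gz")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  b2 <- read_phantom(dir)
  expect_equal(b2$admission_ct$voxels, b$admission_ct$voxels,
               ignore_attr = TRUE)
  expect_equal(b2$admission_ct$spacing_mm, b$admission_ct$spacing_mm)
  expect_identical(b2$ischemic_mask, b$ischemic_mask)
  expect_equal(b2$truth$pcore_ml, b$truth$pcore_ml)
  expect_equal(b2$truth$true_nwu_pct, b$truth$true_nwu_pct)
})
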