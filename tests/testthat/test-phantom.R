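test_that("airway tree templates respect topology and determinism", {
  single <- build_airway_tree("single")
  tt <- as.data.frame(single)
  expect_equal(nrow(tt), 1)
  expect_equal(tt$generation, 1L)

  t1 <- build_airway_tree("five_lobe", seed = 42)
  t2 <- build_airway_tree("five_lobe", seed = 42)
  expect_identical(t1, t2)

  expect_error(build_airway_tree(per_generation_diameters = c(5, 6, 3)),
               "decreasing")
  expect_error(build_airway_tree(wall_fraction = 1.2), "0, 1")

  tt <- as.data.frame(t1)
  ## every lobe holds at least one branch in the 3.5 +/- 0.25 mm class
  in_class <- tt[abs(tt$lumen_diameter_mm - 3.5) <= 0.25, ]
  expect_setequal(unique(in_class$lobe), c("LUL", "LLL", "RUL", "RML", "RLL"))
  ## child generation = parent generation + 1
  ids <- tt$branch_id
  for (i in seq_len(nrow(tt))) {
    if (!is.na(tt$parent_id[i])) {
      expect_equal(tt$generation[i],
                   tt$generation[match(tt$parent_id[i], ids)] + 1L)
    }
  }
})

test_that("rasterized tube has air in the lumen and tissue in the wall", {
  acq <- acquisition_cropped(40, noise_sd_hu = 0, psf_fwhm_mm = 0,
                             slice_thickness_mm = 0.7)
  tree <- single_tube_tree(3.5, 0.6, length_mm = 20)
  truth <- phantom_truth(trachea_offset_hu = 10, parenchyma_sd_hu = 0,
                         seed = 1)
  ras <- rasterize_phantom(tree, truth, acq)
  ## voxel at the tube axis: pure lumen air plus the calibration drift
  mid <- c(0, 0, 10)
  expect_equal(interp_volume(ras$ct, matrix(mid, 1)), -990,
               tolerance = 0.5)
  ## a parenchymal point away from the wall
  par_pt <- c(0, 5, 10)
  expect_equal(interp_volume(ras$ct, matrix(par_pt, 1)), -870,
               tolerance = 1)
  ## labels: lumen code along the axis
  legend <- label_legend()
  ctr_idx <- round((mid - ras$labels$origin_mm) / ras$labels$spacing_mm) + 1
  expect_equal(ras$labels$labels[ctr_idx[1], ctr_idx[2], ctr_idx[3]],
               legend[["airway_lumen"]])
})

test_that("emphysema-free parenchyma has no low-attenuation voxels pre-noise", {
  acq <- acquisition_cropped(40, noise_sd_hu = 0)
  tree <- single_tube_tree(3.5, 0.6, length_mm = 15)
  truth <- phantom_truth(emphysema_fraction = 0, seed = 3)
  ras <- rasterize_phantom(tree, truth, acq, keep_clean = TRUE)
  lung <- lung_mask_excluding_airways(ras$labels)
  expect_equal(sum(ras$clean$voxels[lung] < -950), 0)
  expect_equal(ras$truth$emphysema_voxel_fraction, 0)
})

test_that("blur and noise leave the label volume untouched", {
  tree <- single_tube_tree(3.5, 0.6, length_mm = 12)
  truth <- phantom_truth(seed = 5)
  a1 <- acquisition_cropped(40, noise_sd_hu = 0, psf_fwhm_mm = 0,
                            slice_thickness_mm = 0.7, seed = 1)
  a2 <- acquisition_cropped(40, noise_sd_hu = 40, psf_fwhm_mm = 1.2, seed = 9)
  r1 <- rasterize_phantom(tree, truth, a1)
  r2 <- rasterize_phantom(tree, truth, a2)
  expect_identical(r1$labels$labels, r2$labels$labels)
  expect_false(identical(r1$ct$voxels, r2$ct$voxels))
})

test_that("the phantom is bit-reproducible under a fixed seed", {
  acq <- acquisition_cropped(40, noise_sd_hu = 25, seed = 7)
  tree <- single_tube_tree(3.5, 0.6, length_mm = 12)
  truth <- phantom_truth(emphysema_fraction = 0.03, seed = 11)
  r1 <- rasterize_phantom(tree, truth, acq)
  r2 <- rasterize_phantom(tree, truth, acq)
  expect_identical(r1$ct$voxels, r2$ct$voxels)
  expect_identical(r1$labels$labels, r2$labels$labels)
  expect_identical(r1$truth$truth_perc15_hu, r2$truth$truth_perc15_hu)
})

test_that("more emphysema strictly lowers the ground-truth Perc15", {
  p15 <- vapply(c(0, 0.05, 0.15, 0.3), function(f) {
    lung_phantom(emph = f, noise = 0, seed = 4)$truth$truth_perc15_hu
  }, numeric(1))
  expect_true(all(diff(p15) < 0))
})

test_that("a tree wider than the field of view is rejected by name", {
  tree <- single_tube_tree(3.5, 0.6, length_mm = 30, axis = c(1, 0, 0))
  acq <- acquisition_cropped(20)
  expect_error(rasterize_phantom(tree, phantom_truth(), acq),
               "field of view")
})

test_that("dose pairs share geometry and differ only in noise", {
  tree <- single_tube_tree(3.5, 0.6, length_mm = 12)
  truth <- phantom_truth(seed = 8)
  al <- acquisition_cropped(40, noise_sd_hu = 25, seed = 21)
  ah <- acquisition_cropped(40, noise_sd_hu = 10, seed = 22)
  dp <- generate_dose_pair(tree, truth, al, ah)
  expect_identical(dim(dp$ct_low$voxels), dim(dp$ct_high$voxels))
  ## zero noise at both doses degenerates to identical volumes
  a0 <- acquisition_cropped(40, noise_sd_hu = 0, seed = 1)
  dp0 <- generate_dose_pair(tree, truth, a0, a0)
  expect_identical(dp0$ct_low$voxels, dp0$ct_high$voxels)
  ## low dose must not be cleaner than high dose
  expect_error(generate_dose_pair(tree, truth, ah, al), "noise")
  ## geometry mismatch
  expect_error(generate_dose_pair(tree, truth, al,
                                  acquisition_cropped(60, noise_sd_hu = 5)),
               "geometry")
})
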