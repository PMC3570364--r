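const_vol <- function(value, dims = c(12, 12, 12)) {
  ct_volume(array(value, dims), c(1, 1, 1))
}

test_that("trachea recalibration shifts the whole scan to -1000 air", {
  v <- const_vol(-1000)
  mask <- array(TRUE, dim(v$voxels))
  rc <- recalibrate_hu(v, mask)
  expect_equal(rc$calibration_shift_hu, 0)
  expect_identical(rc$ct$voxels, v$voxels)
  v2 <- const_vol(-975)
  rc2 <- recalibrate_hu(v2, mask)
  expect_equal(rc2$calibration_shift_hu, -25)
  expect_equal(unique(as.vector(rc2$ct$voxels)), -1000)
  expect_error(recalibrate_hu(v, array(FALSE, dim(v$voxels))), "empty")
})

test_that("Perc15 follows the interpolated-order-statistic convention", {
  ## constant field
  m <- array(TRUE, c(12, 12, 12))
  expect_equal(compute_perc15(const_vol(-900), m), -900)
  ## 1000 distinct values: -1000 + (0..999) -> -850.15 under type 7
  v <- ct_volume(array(-1000 + (0:999), c(10, 10, 10)), c(1, 1, 1))
  expect_equal(compute_perc15(v, array(TRUE, c(10, 10, 10))), -850.15)
  ## shift equivariance without recalibration
  v2 <- ct_volume(v$voxels + 37, c(1, 1, 1))
  expect_equal(compute_perc15(v2, array(TRUE, c(10, 10, 10))),
               -850.15 + 37)
  expect_error(compute_perc15(v, array(FALSE, c(10, 10, 10))), "100")
})

test_that("Perc15 matches a sort-based percentile oracle on random masks", {
  set.seed(99)
  for (rep in 1:6) {
    n <- sample(500:5000, 1)
    dims <- c(20, 20, 25)
    vox <- array(rnorm(prod(dims), -850, 60), dims)
    mask <- array(FALSE, dims)
    mask[sample(prod(dims), n)] <- TRUE
    x <- sort(vox[mask])
    ## hand-written type-7 interpolation
    h <- (n - 1) * 0.15 + 1
    oracle <- x[floor(h)] + (h - floor(h)) * (x[floor(h) + 1] - x[floor(h)])
    expect_lt(abs(compute_perc15(ct_volume(vox, c(1, 1, 1)), mask) - oracle),
              1e-9)
  }
})

test_that("%LAA-950 counts low-attenuation voxels with a log floor", {
  dims <- c(10, 10, 10)
  vox <- array(-900, dims)
  vox[1:150] <- -960
  v <- ct_volume(vox, c(1, 1, 1))
  laa <- compute_laa950(v, array(TRUE, dims))
  expect_equal(laa$laa950_pct, 15)
  expect_equal(laa$log_laa950, log(15))
  ## no low-attenuation voxels: 0% and the floored log
  laa0 <- compute_laa950(const_vol(-900), array(TRUE, c(12, 12, 12)))
  expect_equal(laa0$laa950_pct, 0)
  expect_equal(laa0$log_laa950, log(0.1))
})

test_that("lung volume is voxel count times voxel volume", {
  m <- array(TRUE, c(100, 100, 100))
  expect_equal(compute_lung_volume(m, c(1, 1, 1)), 1)
  expect_equal(compute_lung_volume(array(FALSE, c(5, 5, 5)), c(1, 1, 1)), 0)
  expect_error(compute_lung_volume(m, c(0, 1, 1)), "spacing")
})

test_that("phantom lung volume matches the ellipsoid geometry within 2%", {
  ras <- cached("lung0", lung_phantom(emph = 0, seed = 4))
  geom <- ras$truth$lung_geometry
  v_ell <- 4 / 3 * pi * prod(geom$semiaxes) / 1e6
  ## subtract the lumen chord through the ellipsoid
  v_lumen <- pi * 1.75^2 * 28 / 1e6
  expect_equal(compute_lung_volume(ras$labels), v_ell - v_lumen,
               tolerance = 0.02)
})

test_that("recalibration makes densitometry invariant to global drift", {
  base <- cached("lung5", lung_phantom(emph = 0.05, seed = 2))
  for (off in c(-50, 25, 50)) {
    shifted <- lung_phantom(emph = 0.05, offset = off, seed = 2)
    d0 <- quantify_densitometry(base$ct, base$labels)
    d1 <- quantify_densitometry(shifted$ct, shifted$labels)
    expect_equal(d1$perc15_hu, d0$perc15_hu, tolerance = 1e-6)
    expect_equal(d1$laa950_pct, d0$laa950_pct, tolerance = 1e-6)
    expect_equal(d1$calibration_shift_hu - d0$calibration_shift_hu, -off,
                 tolerance = 1e-6)
  }
})

test_that("measured %LAA tracks the phantom emphysema fraction", {
  ras <- cached("lung5", lung_phantom(emph = 0.05, seed = 2))
  dens <- quantify_densitometry(ras$ct, ras$labels)
  truth_pct <- 100 * ras$truth$emphysema_voxel_fraction
  ## tolerance: one surface-voxel layer over the placed blobs
  mean_r <- mean(ras$truth$blob_radii_mm)
  layer <- truth_pct * 3 * mean(ras$labels$spacing_mm) / mean_r
  expect_lt(abs(dens$laa950_pct - truth_pct), layer)
  expect_gt(dens$laa950_pct, 0.5 * truth_pct)
})

test_that("more emphysema lowers Perc15 and raises %LAA monotonically", {
  dens <- lapply(c("lung0", "lung5", "lung15"), function(k) {
    ras <- cached(k, switch(k,
      lung0 = lung_phantom(emph = 0, seed = 4),
      lung5 = lung_phantom(emph = 0.05, seed = 2),
      lung15 = lung_phantom(emph = 0.15, seed = 2)))
    quantify_densitometry(ras$ct, ras$labels)
  })
  p15 <- vapply(dens, function(d) d$perc15_hu, numeric(1))
  laa <- vapply(dens, function(d) d$laa950_pct, numeric(1))
  expect_true(all(diff(p15) < 0))
  expect_true(all(diff(laa) > 0))
})
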