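radii_grid <- seq(0, 6, by = 0.05)

test_that("inner border detection finds the half-maximum crossing", {
  ## edge midway between two samples: sub-step interpolation is exact
  prof <- ideal_profile(radii_grid, 1.775, 0.6)
  expect_equal(detect_inner_border(radii_grid, prof, -1000, 0), 1.775)
  ## grid-aligned edge: correct to within half a sampling step
  prof2 <- ideal_profile(radii_grid, 1.75, 0.6)
  expect_lt(abs(detect_inner_border(radii_grid, prof2, -1000, 0) - 1.75),
            0.05 / 2 + 1e-12)
  ## all-air ray: no crossing
  expect_true(is.na(detect_inner_border(radii_grid,
                                        rep(-1000, length(radii_grid)),
                                        -1000, 0)))
})

test_that("a symmetrically blurred edge keeps its half-maximum position", {
  fine <- seq(-2, 8, by = 0.002)
  step_prof <- ifelse(fine < 1.75, -1000, 0)
  for (sigma in c(0.2, 0.3, 0.45)) {
    hu <- blur_profile_1d(fine, step_prof, sigma, radii_grid)
    inner <- detect_inner_border(radii_grid, hu, -1000, 0)
    expect_equal(inner, 1.75, tolerance = 0.026)
  }
})

test_that("wall integral recovers box width exactly and under blur", {
  ## unblurred box with edges between samples: exact width
  prof <- ideal_profile(radii_grid, 1.775, 0.6, hu_par = -1000)
  inner <- detect_inner_border(radii_grid, prof, -1000, 0)
  expect_equal(measure_wall_ibwt(radii_grid, prof, inner, -1000, 0, -1000),
               0.6, tolerance = 1e-9)
  ## blurred with sigma 0.4 mm, air both sides: integral preserved
  fine <- seq(-2, 8, by = 0.002)
  box <- ifelse(fine >= 1.75 & fine < 2.35, 0, -1000)
  hu <- blur_profile_1d(fine, box, 0.4, radii_grid)
  inner <- detect_inner_border(radii_grid, hu, -1000, max(hu))
  expect_equal(measure_wall_ibwt(radii_grid, hu, inner, -1000, 0, -1000,
                                 window_mm = 2),
               0.6, tolerance = 0.02)
  ## asymmetric baselines: air inside, parenchyma outside
  box2 <- ideal_profile(fine, 1.75, 0.6)
  hu2 <- blur_profile_1d(fine, box2, 0.4, radii_grid)
  inner2 <- detect_inner_border(radii_grid, hu2, -1000, max(hu2))
  expect_equal(measure_wall_ibwt(radii_grid, hu2, inner2, -1000, 0, -880,
                                 window_mm = 2),
               0.6, tolerance = 0.05)
  ## reference density below the baselines is a configuration error
  expect_error(measure_wall_ibwt(radii_grid, prof, inner, -1000, -900, -880),
               "exceed")
})

test_that("outer border detectability follows the descent criterion", {
  prof <- ideal_profile(radii_grid, 1.75, 0.6)  # clean outer edge
  expect_true(assess_outer_border(radii_grid, prof, 2.05, -880, 0))
  ## adjacent wall-density tissue: no descent within reach
  plateau <- ifelse(radii_grid < 1.75, -1000, 0)
  expect_false(assess_outer_border(radii_grid, plateau, 2.05, -880, 0))
  ## empty search window
  expect_false(assess_outer_border(radii_grid, prof, 2.05, -880, 0,
                                   d_max_mm = 0))
})

test_that("cross-section summary computes diameter, AWT and APF", {
  nr <- 8L
  ## circular lumen, all rays assessed
  hu <- t(replicate(nr, ideal_profile(radii_grid, 1.775, 0.6)))
  s <- summarize_cross_section(make_cross_section(hu, radii_grid))
  expect_equal(s$internal_diameter_mm, 3.55, tolerance = 1e-9)
  expect_equal(s$apf_local, 1)
  expect_equal(s$awt_mm, 0.6, tolerance = 1e-9)
  ## two assessed rays (walls 0.5 and 0.7), six occluded: mean AWT and APF
  mk <- function(w, occluded) {
    if (occluded) ifelse(radii_grid < 1.775, -1000, 0) else
      ideal_profile(radii_grid, 1.775, w)
  }
  hu2 <- rbind(mk(0.5, FALSE), mk(0.7, FALSE),
               t(replicate(6, mk(0.6, TRUE))))
  s2 <- summarize_cross_section(make_cross_section(hu2, radii_grid))
  expect_equal(s2$awt_mm, 0.6, tolerance = 1e-9)
  expect_equal(s2$apf_local, 0.25)
  ## occlusion leaves the inner border (hence the diameter) unchanged
  expect_equal(s2$internal_diameter_mm, s$internal_diameter_mm,
               tolerance = 0.01)
})

test_that("elliptical lumens use the mean-radius diameter convention", {
  a <- 2.0; b <- 1.5
  nr <- 32L
  theta <- 2 * pi * (seq_len(nr) - 1) / nr
  r_ell <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  hu <- t(sapply(r_ell, function(r) ideal_profile(radii_grid, r, 0.6)))
  s <- summarize_cross_section(make_cross_section(hu, radii_grid))
  ## oracle: twice the mean ray radius, not the equal-area diameter
  expect_equal(s$internal_diameter_mm, 2 * mean(r_ell), tolerance = 0.02)
  expect_false(isTRUE(all.equal(2 * mean(r_ell), 2 * sqrt(a * b),
                                tolerance = 1e-3)))
})

test_that("fixed-diameter selection applies the tolerance and APF rules", {
  locs <- data.frame(
    branch_id = 1:5, generation = 3L, lobe = "RUL", position_mm = 1:5,
    internal_diameter_mm = c(3.0, 3.3, 3.5, 3.8, 3.5),
    awt_mm = 0.6, apf_local = c(1, 1, 1, 1, 0.20), n_rays = 32L
  )
  sel <- select_fixed_diameter_locations(locs, 3.5, 0.25, 0.25)
  expect_setequal(sel$internal_diameter_mm, c(3.3, 3.5))
  ## the location with APF 0.20 is excluded despite matching diameter
  expect_false(5 %in% sel$branch_id)
  ## zero tolerance keeps only the exact diameter
  sel0 <- select_fixed_diameter_locations(locs, 3.5, 0, 0.25)
  expect_equal(nrow(sel0), 1)
})

test_that("perimeter-to-diameter reproduces the pi10 equivalence", {
  expect_equal(round(perimeter_to_diameter(10), 1), 3.2)
  expect_equal(perimeter_to_diameter(pi), 1)
  expect_equal(perimeter_to_diameter(0), 0)
  expect_error(perimeter_to_diameter(-1), "non-negative")
})

test_that("lobe aggregation is the APF-weighted five-lobe mean", {
  locs <- data.frame(
    lobe = c("LUL", "LUL", "RLL"),
    awt_mm = c(0.5, 0.5, 0.7),
    apf_local = c(60, 40, 50)
  )
  agg <- aggregate_lobes(locs)
  expect_equal(agg$lobes$awt_mm[agg$lobes$lobe == "LUL"], 0.5)
  expect_equal(agg$awt_mm, (0.5 * 100 + 0.7 * 50) / 150)
  expect_equal(agg$apf_total, 150)
  ## single lobe: whole lung equals that lobe
  one <- aggregate_lobes(locs[locs$lobe == "RLL", ])
  expect_equal(one$awt_mm, 0.7)
  ## equal lobe APFs: plain mean of lobe AWTs
  eq <- data.frame(lobe = c("LUL", "LLL", "RUL"), awt_mm = c(0.4, 0.6, 0.8),
                   apf_local = 10)
  expect_equal(aggregate_lobes(eq)$awt_mm, 0.6)
  ## whole-lung value is bounded by the lobe values
  expect_true(agg$awt_mm >= min(agg$lobes$awt_mm) &&
                agg$awt_mm <= max(agg$lobes$awt_mm))
  ## zero total APF is undefined
  z <- data.frame(lobe = "LUL", awt_mm = 0.5, apf_local = 0)
  expect_error(aggregate_lobes(z), "APF")
})

test_that("location generations come from topological tree depth", {
  tree <- build_airway_tree("five_lobe", seed = 2)
  tt <- as.data.frame(tree)
  root <- tt$branch_id[tt$generation == 0]
  expect_equal(generation_of_location(list(branch_id = root), tree), 0L)
  g2 <- tt$branch_id[tt$generation == 2][1]
  expect_equal(generation_of_location(list(branch_id = g2), tree), 2L)
  expect_error(generation_of_location(list(branch_id = 9999), tree),
               "not in the tree")
})

test_that("cross-section sampling is endpoint-inclusive and interpolating", {
  ras <- cached("tube06", tube_phantom())
  cl <- list(branch_id = 1, generation = 1L, lobe = "RUL",
             points = cbind(0, 0, seq(2, 12, length.out = 21)),
             tangents = matrix(rep(c(0, 0, 1), 21), ncol = 3, byrow = TRUE))
  secs <- sample_cross_sections(ras$ct, cl, step_mm = 1)
  expect_length(secs, 11)  # 10 mm at 1 mm steps, both ends included
  expect_equal(secs[[1]]$position_mm, 0)
  expect_equal(secs[[11]]$position_mm, 10)
  ## rays of an axial tube stay in their slice plane
  expect_equal(secs[[5]]$tangent, c(0, 0, 1), tolerance = 1e-9)
})
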