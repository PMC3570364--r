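## Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## straight 3.5 mm tube at protocol spacing
tube_phantom <- function(wall = 0.6, noise = 25, fwhm = 0.7,
                         lumen = 3.5, length_mm = 20, offset = 0,
                         seed = 1) {
  acq <- acquisition_cropped(40, noise_sd_hu = noise, psf_fwhm_mm = fwhm,
                             seed = seed)
  tree <- single_tube_tree(lumen, wall, length_mm = length_mm)
  truth <- phantom_truth(trachea_offset_hu = offset, seed = seed + 100)
  c(rasterize_phantom(tree, truth, acq), list(tree = tree))
}

## tube inside an ellipsoidal lung, for densitometry
lung_phantom <- function(emph = 0, noise = 25, offset = 0, seed = 2) {
  acq <- acquisition_cropped(46, noise_sd_hu = noise, seed = seed)
  tree <- single_tube_tree(3.5, 0.6, length_mm = 30, origin = c(0, 0, -15))
  lung <- list(type = "ellipsoid", center = c(0, 0, 0),
               semiaxes = c(18, 18, 14), lobe = "RUL")
  truth <- phantom_truth(emphysema_fraction = emph,
                         trachea_offset_hu = offset, seed = seed + 50)
  rasterize_phantom(tree, truth, acq, lung = lung)
}

## measured location table of one tube phantom
measure_tube <- function(ras) {
  measure_airways(ras$ct, ras$labels)
}

## 1D blur oracle: box/step profiles convolved with a Gaussian on a fine
## grid, resampled to the ray grid
blur_profile_1d <- function(fine_x, prof, sigma, radii) {
  if (sigma > 0) {
    dx <- fine_x[2] - fine_x[1]
    k <- dnorm(seq(-4 * sigma, 4 * sigma, by = dx), sd = sigma)
    k <- k / sum(k)
    pad <- length(k)
    prof <- c(rep(prof[1], pad), prof, rep(prof[length(prof)], pad))
    prof <- stats::filter(prof, k, sides = 2)
    prof <- prof[(pad + 1):(pad + length(fine_x))]
  }
  approx(fine_x, prof, xout = radii)$y
}

## synthetic cross_section built from per-ray profiles (matrix rays x r)
make_cross_section <- function(hu, radii, lobe = "RUL", generation = 3L) {
  structure(
    list(branch_id = 1, generation = generation, lobe = lobe,
         position_index = 1L, position_mm = 0, center = c(0, 0, 0),
         tangent = c(0, 0, 1), radii = radii, hu = hu,
         n_rays = nrow(hu), step_mm = radii[2] - radii[1]),
    class = "cross_section"
  )
}

## ideal radial profile of a circular airway: air to inner radius, wall
## to outer radius, parenchyma beyond (sharp, unblurred)
ideal_profile <- function(radii, r_in, wall, hu_air = -1000, hu_wall = 0,
                          hu_par = -880) {
  ifelse(radii < r_in, hu_air, ifelse(radii < r_in + wall, hu_wall, hu_par))
}
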