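## Run configuration: every default is the protocol's printed constant
## (3.5 mm target diameter, +/- 0.25 mm tolerance, >= 25% assessed
## perimeter, -950 HU low-attenuation threshold, 15th percentile).

#' Measurement and densitometry configuration
#'
#' @param target_diameter_mm Fixed internal lumen diameter, mm.
#' @param tol_mm Diameter tolerance, mm.
#' @param min_apf Minimum assessed perimeter fraction for inclusion.
#' @param n_rays Rays per cross-section.
#' @param centerline_step_mm Cross-section spacing along centerlines, mm.
#' @param ray_len_mm,ray_step_mm Radial profile extent and step, mm.
#' @param wall_hu_ref Unblurred wall tissue reference density for the
#'   thickness integral, HU (soft tissue, 0 HU).
#' @param window_mm Integration margin around the wall, mm.
#' @param f_out,d_max_mm Outer-border detectability: required descent
#'   fraction toward parenchyma and search distance beyond the peak.
#' @param trim_mm Centerline margin skipped near junctions, mm.
#' @param laa_threshold_hu Low-attenuation threshold, HU.
#' @param perc_percentile Densitometry percentile.
#' @param seed Integer seed for any stochastic stage.
#' @return Named list of class `ct_config`.
#' @export
ct_config <- function(target_diameter_mm = 3.5, tol_mm = 0.25,
                      min_apf = 0.25, n_rays = 32L,
                      centerline_step_mm = 1, ray_len_mm = 6,
                      ray_step_mm = 0.1, wall_hu_ref = 0, window_mm = 2,
                      f_out = 0.5, d_max_mm = 2, trim_mm = 2,
                      laa_threshold_hu = -950, perc_percentile = 15,
                      seed = 1L) {
  stopifnot(target_diameter_mm > 0, tol_mm >= 0, min_apf >= 0, min_apf <= 1,
            n_rays >= 8, centerline_step_mm > 0, ray_step_mm > 0,
            ray_len_mm > ray_step_mm, perc_percentile > 0,
            perc_percentile < 100)
  structure(
    list(target_diameter_mm = target_diameter_mm, tol_mm = tol_mm,
         min_apf = min_apf, n_rays = as.integer(n_rays),
         centerline_step_mm = centerline_step_mm, ray_len_mm = ray_len_mm,
         ray_step_mm = ray_step_mm, wall_hu_ref = wall_hu_ref,
         window_mm = window_mm, f_out = f_out, d_max_mm = d_max_mm,
         trim_mm = trim_mm, laa_threshold_hu = laa_threshold_hu,
         perc_percentile = perc_percentile, seed = as.integer(seed)),
    class = "ct_config"
  )
}
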