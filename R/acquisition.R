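## Acquisition geometry of the low-dose screening protocol:
## 512x512 matrix, FOV 300-350 mm, 1 mm slices reconstructed at 0.7 mm
## increment with a soft kernel. The soft kernel is modelled as an
## isotropic in-plane Gaussian PSF plus slice-direction averaging over
## the slice thickness.

#' In-plane pixel spacing from field of view and matrix size
#'
#' @param fov_mm In-plane field of view, mm.
#' @param matrix Reconstruction matrix edge (e.g. 512).
#' @return Pixel spacing in mm (`fov_mm / matrix`).
#' @examples
#' pixel_spacing_from_fov(300, 512)  # 0.586 mm
#' pixel_spacing_from_fov(350, 512)  # 0.684 mm
#' @export
pixel_spacing_from_fov <- function(fov_mm, matrix) {
  if (!is_scalar_num(fov_mm) || fov_mm <= 0) {
    stop_domain("fov_mm must be a positive length")
  }
  if (!is_scalar_num(matrix) || matrix < 1) {
    stop_domain("matrix must be a positive integer")
  }
  fov_mm / matrix
}

#' Acquisition specification
#'
#' Bundles reconstruction geometry, the point-spread-function surrogate
#' for the soft reconstruction kernel, and the additive noise scale.
#' Defaults follow the screening protocol (low-dose scan).
#'
#' @param fov_mm In-plane field of view, mm.
#' @param matrix Reconstruction matrix edge.
#' @param slice_thickness_mm Slice thickness, mm.
#' @param slice_increment_mm Slice increment (z spacing), mm; must not
#'   exceed the slice thickness.
#' @param psf_fwhm_mm Full width at half maximum of the in-plane Gaussian
#'   PSF, mm.
#' @param noise_sd_hu Additive Gaussian noise standard deviation, HU.
#'   25 HU emulates a 20 mAs low-dose scan, 10 HU a diagnostic-dose scan.
#' @param seed Integer seed for the noise realization.
#' @return An `acquisition_spec` object.
#' @export
acquisition_spec <- function(fov_mm = 300, matrix = 512L,
                             slice_thickness_mm = 1, slice_increment_mm = 0.7,
                             psf_fwhm_mm = 0.7, noise_sd_hu = 25, seed = 1L) {
  if (fov_mm <= 0) stop_domain("fov_mm must be positive")
  if (matrix < 64) stop_domain("matrix must be at least 64")
  if (slice_increment_mm > slice_thickness_mm) {
    stop_domain("slice_increment_mm must not exceed slice_thickness_mm")
  }
  if (noise_sd_hu < 0) stop_domain("noise_sd_hu must be non-negative")
  structure(
    list(fov_mm = fov_mm, matrix = as.integer(matrix),
         slice_thickness_mm = slice_thickness_mm,
         slice_increment_mm = slice_increment_mm,
         psf_fwhm_mm = psf_fwhm_mm, noise_sd_hu = noise_sd_hu,
         seed = as.integer(seed)),
    class = "acquisition_spec"
  )
}

#' Acquisition at protocol voxel spacing on a reduced field of view
#'
#' Keeps the protocol pixel spacing (FOV/matrix of the full scan) while
#' covering only `extent_mm` in plane, so small phantoms rasterize to
#' small grids without changing resolution.
#'
#' @param extent_mm In-plane extent to cover, mm.
#' @param pixel_mm Target pixel spacing, mm (protocol default 300/512).
#' @param ... Passed to [acquisition_spec()].
#' @return An `acquisition_spec`.
#' @export
acquisition_cropped <- function(extent_mm, pixel_mm = 300 / 512, ...) {
  m <- max(64L, as.integer(ceiling(extent_mm / pixel_mm)))
  acquisition_spec(fov_mm = m * pixel_mm, matrix = m, ...)
}
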