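## CT and label volume containers.
##
## A volume is a plain 3D array plus spacing and origin, axis order
## (x, y, z) with z the slice direction. World coordinates are in mm;
## voxel (i, j, k) (1-based in R) has world position
## origin + (i-1, j-1, k-1) * spacing.

#' Construct a CT volume
#'
#' @param voxels 3D numeric array of Hounsfield units.
#' @param spacing_mm Numeric length-3 voxel spacing (dx, dy, dz), mm.
#' @param origin_mm Numeric length-3 world position of voxel (1,1,1), mm.
#' @return A `ct_volume` object.
#' @export
ct_volume <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) stop_domain("voxels must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    stop_domain("spacing_mm must be 3 positive lengths")
  }
  structure(
    list(voxels = voxels, spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, HU range [%.0f, %.0f]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing_mm, 3), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Standard label legend for phantom and measurement volumes
#'
#' Codes 1-5 are the five lung lobes, 6 the trachea air column, 7 the
#' bronchial airway lumen, 0 everything else.
#' @return Named integer vector mapping region names to label codes.
#' @export
label_legend <- function() {
  c(outside = 0L, LUL = 1L, LLL = 2L, RUL = 3L, RML = 4L, RLL = 5L,
    trachea = 6L, airway_lumen = 7L)
}

#' Construct a label volume
#'
#' @param labels 3D integer array of region codes.
#' @param spacing_mm,origin_mm As in [ct_volume()].
#' @param legend Named integer vector (see [label_legend()]).
#' @return A `label_volume` object.
#' @export
label_volume <- function(labels, spacing_mm, origin_mm = c(0, 0, 0),
                         legend = label_legend()) {
  if (length(dim(labels)) != 3L) stop_domain("labels must be a 3D array")
  structure(
    list(labels = labels, spacing_mm = as.numeric(spacing_mm),
         origin_mm = as.numeric(origin_mm), legend = legend),
    class = "label_volume"
  )
}

lobe_codes <- function(legend = label_legend()) {
  legend[c("LUL", "LLL", "RUL", "RML", "RLL")]
}

## world mm -> fractional 0-based voxel index
world_to_index <- function(vol, pts) {
  sweep(sweep(pts, 2, vol$origin_mm, "-"), 2, vol$spacing_mm, "/")
}

index_to_world <- function(vol, idx) {
  sweep(sweep(idx, 2, vol$spacing_mm, "*"), 2, vol$origin_mm, "+")
}

#' Trilinear interpolation of a volume at world points
#'
#' Points at voxel centers reproduce the stored value exactly; points
#' outside the grid return NA.
#'
#' @param vol A `ct_volume`.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return Numeric vector of interpolated HU values.
#' @export
interp_volume <- function(vol, pts) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3)
  idx <- world_to_index(vol, pts)
  dm <- dim(vol$voxels)
  eps <- 1e-6  # tolerate round-off exactly on the grid faces
  out <- rep(NA_real_, nrow(pts))
  ok <- idx[, 1] >= -eps & idx[, 1] <= dm[1] - 1 + eps &
    idx[, 2] >= -eps & idx[, 2] <= dm[2] - 1 + eps &
    idx[, 3] >= -eps & idx[, 3] <= dm[3] - 1 + eps
  if (!any(ok)) return(out)
  idx <- sweep(pmax(idx, 0), 2, dm - 1, pmin)
  i0 <- floor(idx)[ok, , drop = FALSE]
  ## clamp the base cell so points exactly on the far face interpolate
  i1 <- pmin(i0 + 1, matrix(dm - 1, nrow(i0), 3, byrow = TRUE))
  i0 <- pmin(i0, matrix(dm - 2, nrow(i0), 3, byrow = TRUE))
  i0 <- pmax(i0, 0)
  f <- idx[ok, , drop = FALSE] - i0
  v <- vol$voxels
  at <- function(ix, iy, iz) v[cbind(ix + 1, iy + 1, iz + 1)]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  c00 <- at(i0[, 1], i0[, 2], i0[, 3]) * (1 - fx) + at(i1[, 1], i0[, 2], i0[, 3]) * fx
  c10 <- at(i0[, 1], i1[, 2], i0[, 3]) * (1 - fx) + at(i1[, 1], i1[, 2], i0[, 3]) * fx
  c01 <- at(i0[, 1], i0[, 2], i1[, 3]) * (1 - fx) + at(i1[, 1], i0[, 2], i1[, 3]) * fx
  c11 <- at(i0[, 1], i1[, 2], i1[, 3]) * (1 - fx) + at(i1[, 1], i1[, 2], i1[, 3]) * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

## Separable convolution of a 3D array along one axis with a small kernel,
## replicate-edge padding, implemented by shifted index sums.
convolve_axis <- function(a, kernel, axis) {
  n <- dim(a)[axis]
  half <- (length(kernel) - 1L) / 2L
  out <- array(0, dim(a))
  for (t in seq_along(kernel)) {
    off <- t - 1L - half
    src <- clamp(seq_len(n) + off, 1L, n)
    out <- out + kernel[t] * switch(axis,
      a[src, , , drop = FALSE],
      a[, src, , drop = FALSE],
      a[, , src, drop = FALSE])
  }
  out
}

gaussian_kernel <- function(sigma_vox) {
  if (sigma_vox <= 1e-6) return(1)
  half <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-half):half)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

boxcar_kernel <- function(width_vox) {
  if (width_vox <= 1) return(1)
  half <- ceiling((width_vox - 1) / 2)
  x <- (-half):half
  ## fractional coverage of each tap by a boxcar of the given width
  k <- pmin(x + 0.5, width_vox / 2) - pmax(x - 0.5, -width_vox / 2)
  k <- pmax(k, 0)
  k / sum(k)
}
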