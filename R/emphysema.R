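## Trachea-recalibrated lung densitometry: Perc15, %LAA-950, lung volume.
##
## Densities of the entire scan are recalibrated by shifting all HU so
## that mean air density in the trachea becomes -1000 HU; airway lumen
## voxels (dilated by one voxel to strip partial-volume rims) are
## excluded from the parenchymal density distribution.

#' Recalibrate scan densities against tracheal air
#'
#' @param ct A `ct_volume`.
#' @param trachea_mask Logical 3D array marking tracheal air voxels, or a
#'   `label_volume` (its `trachea` code; when no voxel carries it, e.g. a
#'   tube phantom without a trachea, the airway lumen air is the
#'   reference instead).
#' @return List with `ct` (shifted volume) and `calibration_shift_hu`
#'   (the applied shift, `-1000 - mean(trachea HU)`).
#' @export
recalibrate_hu <- function(ct, trachea_mask) {
  mask <- as_mask(trachea_mask, "trachea")
  if (!any(mask) && inherits(trachea_mask, "label_volume")) {
    mask <- as_mask(trachea_mask, "lumen")
  }
  if (!any(mask)) stop_domain("trachea mask is empty")
  ## average core air only: partial-volume rim voxels next to the wall
  ## would bias the reference upward
  for (i in 1:2) {
    core <- erode1(mask)
    if (!any(core)) break
    mask <- core
  }
  shift <- -1000 - mean(ct$voxels[mask])
  list(ct = ct_volume(ct$voxels + shift, ct$spacing_mm, ct$origin_mm),
       calibration_shift_hu = shift)
}

as_mask <- function(x, what = c("trachea", "lumen", "lung")) {
  what <- match.arg(what)
  if (is.logical(x)) return(x)
  if (is.array(x) && !inherits(x, "label_volume")) return(x != 0)
  legend <- x$legend
  switch(what,
    trachea = x$labels == legend[["trachea"]],
    lumen = x$labels == legend[["trachea"]] |
      x$labels == legend[["airway_lumen"]],
    lung = x$labels >= legend[["LUL"]] & x$labels <= legend[["RLL"]]
  )
}

## binary erosion by one voxel (6-connectivity)
erode1 <- function(mask) !dilate1(!mask)

## binary dilation by one voxel (6-connectivity)
dilate1 <- function(mask) {
  out <- mask
  dm <- dim(mask)
  shift_or <- function(m, axis, by) {
    n <- dm[axis]
    src <- clamp(seq_len(n) - by, 1L, n)
    switch(axis, m[src, , , drop = FALSE], m[, src, , drop = FALSE],
           m[, , src, drop = FALSE])
  }
  for (axis in 1:3) for (by in c(-1L, 1L)) {
    out <- out | shift_or(mask, axis, by)
  }
  out
}

#' Lung mask with airway lumen excluded
#'
#' Lobe-labeled voxels minus the airway/trachea lumen dilated by one
#' voxel (removing partial-volume lumen rims).
#'
#' @param labels A `label_volume`.
#' @return Logical 3D array.
#' @export
lung_mask_excluding_airways <- function(labels) {
  as_mask(labels, "lung") & !dilate1(as_mask(labels, "lumen"))
}

#' 15th-percentile lung density (Perc15)
#'
#' The HU threshold below which 15% of parenchymal voxels fall, using
#' linear interpolation between order statistics (quantile type 7).
#'
#' @param ct A `ct_volume` (recalibrated, see [recalibrate_hu()]).
#' @param lung_mask Logical 3D array of lung voxels with airways
#'   excluded, or a `label_volume` (then
#'   [lung_mask_excluding_airways()] is applied).
#' @param p Percentile, default 15.
#' @return Perc15 in HU.
#' @export
compute_perc15 <- function(ct, lung_mask, p = 15) {
  mask <- resolve_lung_mask(lung_mask)
  n <- sum(mask)
  if (n < 100) stop_domain("need at least 100 lung voxels, got ", n)
  as.numeric(quantile(ct$voxels[mask], p / 100, type = 7, names = FALSE))
}

resolve_lung_mask <- function(lung_mask) {
  if (inherits(lung_mask, "label_volume")) {
    lung_mask_excluding_airways(lung_mask)
  } else {
    lung_mask
  }
}

#' Percentage of low-attenuation area (%LAA-950)
#'
#' Proportion of parenchymal voxels below the threshold (default
#' -950 HU), in percent, with its natural-log transform. %LAA below the
#' floor (default 0.1%) is floored before the log so fully emphysema-free
#' lungs stay finite.
#'
#' @inheritParams compute_perc15
#' @param threshold_hu Low-attenuation threshold, HU.
#' @param log_floor_pct Floor applied before the log transform, %.
#' @return List with `laa950_pct` and `log_laa950`.
#' @export
compute_laa950 <- function(ct, lung_mask, threshold_hu = -950,
                           log_floor_pct = 0.1) {
  mask <- resolve_lung_mask(lung_mask)
  n <- sum(mask)
  if (n < 100) stop_domain("need at least 100 lung voxels, got ", n)
  pct <- 100 * sum(ct$voxels[mask] < threshold_hu) / n
  list(laa950_pct = pct, log_laa950 = log(max(pct, log_floor_pct)))
}

#' Lung volume from a mask
#'
#' @param lung_mask Logical 3D array or `label_volume` (lobe voxels).
#' @param spacing_mm Voxel spacing (required when `lung_mask` is a bare
#'   array).
#' @return Volume in liters (voxel count x voxel volume).
#' @export
compute_lung_volume <- function(lung_mask, spacing_mm = NULL) {
  if (inherits(lung_mask, "label_volume")) {
    spacing_mm <- lung_mask$spacing_mm
    lung_mask <- as_mask(lung_mask, "lung")
  }
  if (is.null(spacing_mm) || any(spacing_mm <= 0)) {
    stop_domain("positive spacing_mm required")
  }
  sum(lung_mask) * prod(spacing_mm) / 1e6
}

#' Full densitometry of one scan
#'
#' Recalibrates against tracheal air, then computes Perc15, %LAA-950
#' (with log transform) over the lung with airways excluded, and the
#' lung volume.
#'
#' @param ct A `ct_volume`.
#' @param labels A `label_volume` with lobe, trachea and lumen codes.
#' @param config A [ct_config()] list (thresholds and percentile).
#' @param recalibrate Apply trachea recalibration first (default TRUE).
#' @return A `densitometry_result` list: `perc15_hu`, `laa950_pct`,
#'   `log_laa950`, `lung_volume_l`, `calibration_shift_hu`. Log
#'   transforms use the natural log.
#' @export
quantify_densitometry <- function(ct, labels, config = ct_config(),
                                  recalibrate = TRUE) {
  shift <- 0
  if (recalibrate) {
    rc <- recalibrate_hu(ct, labels)
    ct <- rc$ct
    shift <- rc$calibration_shift_hu
  }
  mask <- lung_mask_excluding_airways(labels)
  laa <- compute_laa950(ct, mask, threshold_hu = config$laa_threshold_hu)
  structure(
    list(perc15_hu = compute_perc15(ct, mask, p = config$perc_percentile),
         laa950_pct = laa$laa950_pct, log_laa950 = laa$log_laa950,
         lung_volume_l = compute_lung_volume(labels),
         calibration_shift_hu = shift, log_base = "natural"),
    class = "densitometry_result"
  )
}
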