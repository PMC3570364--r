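## Airway wall thickness at fixed internal lumen diameter.
##
## At equally spaced positions along each centerline the volume is
## resampled in the plane perpendicular to the airway: n_rays radial HU
## profiles per cross-section. On each ray the inner border is the
## half-maximum rising crossing (sub-step interpolated); wall thickness
## is the Hounsfield-unit integral across the wall, normalized by a
## soft-tissue wall reference density, which is robust to partial-volume
## blurring (the integral of a blurred profile equals the integral of the
## sharp one). The outer border counts as detectable when the profile
## descends at least halfway back toward parenchymal density within a
## short distance beyond the wall peak: the assessed perimeter fraction
## (APF) of a cross-section is the fraction of rays on which it does.

#' Sample perpendicular cross-sections along a centerline
#'
#' Positions are equally spaced and inclusive of both centerline ends.
#'
#' @param ct A `ct_volume`.
#' @param centerline A `centerline` (or any list with `points`,
#'   `tangents`, and optionally `branch_id`, `generation`, `lobe`).
#' @param step_mm Spacing of cross-sections along the centerline, mm.
#' @param n_rays Number of equally angularly spaced rays (>= 8).
#' @param ray_len_mm Radial profile length, mm.
#' @param ray_step_mm Radial sampling step, mm.
#' @return List of `cross_section` objects with the profile matrix
#'   (`n_rays` x radii), radii, center, and provenance fields.
#' @export
sample_cross_sections <- function(ct, centerline, step_mm = 1, n_rays = 32L,
                                  ray_len_mm = 6, ray_step_mm = 0.1) {
  if (step_mm <= 0) stop_domain("step_mm must be positive")
  if (n_rays < 8) stop_domain("n_rays must be at least 8")
  pts <- centerline$points
  if (is.null(pts) || nrow(pts) < 2) return(list())
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  npos <- floor(L / step_mm) + 1L
  si <- seq(0, L, length.out = max(2L, npos))
  centers <- sapply(1:3, function(k) approx(s, pts[, k], xout = si)$y)
  centers <- matrix(centers, ncol = 3)
  tgs <- centerline$tangents
  tidx <- vapply(si, function(x) which.min(abs(s - x)), integer(1))
  radii <- seq(0, ray_len_mm, by = ray_step_mm)
  theta <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  lapply(seq_along(si), function(i) {
    u <- tgs[tidx[i], ]
    fr <- plane_frame(u)
    dirs <- outer(cos(theta), fr$u) + outer(sin(theta), fr$v)
    pts_all <- kronecker(dirs, matrix(radii, ncol = 1)) +
      matrix(centers[i, ], length(radii) * n_rays, 3, byrow = TRUE)
    hu <- matrix(interp_volume(ct, pts_all), nrow = length(radii))
    structure(
      list(branch_id = centerline$branch_id %||% NA,
           generation = centerline$generation %||% NA,
           lobe = centerline$lobe %||% NA_character_,
           position_index = i, position_mm = si[i],
           center = centers[i, ], tangent = u,
           radii = radii, hu = t(hu), n_rays = n_rays,
           step_mm = ray_step_mm),
      class = "cross_section"
    )
  })
}

#' Inner airway wall border on a radial profile
#'
#' Smallest radius where the normalized profile
#' `(hu - hu_air) / (hu_wall_ref - hu_air)` crosses 0.5 rising, with
#' linear sub-step interpolation. For a symmetric blurred edge the
#' half-maximum stays at the true border.
#'
#' @param radii Increasing radii, mm.
#' @param hu HU samples along the ray.
#' @param hu_air Lumen air density, HU.
#' @param hu_wall_ref Wall reference density for normalization, HU
#'   (typically the ray's own peak, so a crossing always exists when a
#'   wall is present).
#' @return Inner radius in mm, or NA when the profile never crosses
#'   half-maximum (ray unassessed).
#' @export
detect_inner_border <- function(radii, hu, hu_air, hu_wall_ref) {
  denom <- hu_wall_ref - hu_air
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  nprof <- (hu - hu_air) / denom
  nprof[!is.finite(nprof)] <- -Inf
  above <- nprof >= 0.5
  k <- which(!above[-length(above)] & above[-1])
  if (length(k) == 0) return(if (above[1]) radii[1] else NA_real_)
  k <- k[1]
  f <- (0.5 - nprof[k]) / (nprof[k + 1] - nprof[k])
  radii[k] + f * (radii[k + 1] - radii[k])
}

#' Integral-based wall thickness on a radial profile
#'
#' Locates the wall peak beyond the inner border, subtracts a piecewise
#' baseline (lumen air before the peak, parenchyma after), and integrates
#' the clipped normalized excess HU over a window spanning the wall:
#' `thickness = step * sum(clip((hu - b) / (hu_wall_ref - b), 0, 1))`.
#' The integral is preserved under symmetric blurring, which removes the
#' partial-volume bias of edge-to-edge (full-width-at-half-maximum)
#' thickness.
#'
#' @inheritParams detect_inner_border
#' @param inner_radius_mm Inner border from [detect_inner_border()].
#' @param hu_wall_ref Unblurred wall tissue reference density, HU; must
#'   exceed both baselines.
#' @param hu_parenchyma Outer baseline density, HU.
#' @param window_mm Integration margin inward of the inner border and
#'   outward of the wall peak, mm.
#' @param peak_search_mm How far beyond the inner border to search for
#'   the wall peak, mm.
#' @param details Also return the wall peak radius and the centroid of
#'   the integrand (the wall center, itself blur-invariant for a
#'   symmetric PSF).
#' @param peak_tol_hu Tolerance below the profile maximum used to place
#'   the wall peak at the onset of the maximal region; raise it by the
#'   image noise level so noise-inflated maxima do not pull the peak
#'   onto the rising flank.
#' @return Wall thickness, mm (NA when no inner border); with
#'   `details = TRUE`, a list `(thickness_mm, r_peak_mm, center_mm)`.
#' @export
measure_wall_ibwt <- function(radii, hu, inner_radius_mm, hu_air,
                              hu_wall_ref, hu_parenchyma, window_mm = 2,
                              peak_search_mm = 2, details = FALSE,
                              peak_tol_hu = 25) {
  none <- if (details) {
    list(thickness_mm = NA_real_, r_peak_mm = NA_real_, center_mm = NA_real_)
  } else NA_real_
  if (is.na(inner_radius_mm)) return(none)
  if (hu_wall_ref <= max(hu_air, hu_parenchyma)) {
    stop_domain("hu_wall_ref must exceed both baseline densities")
  }
  step <- radii[2] - radii[1]
  in_search <- radii > inner_radius_mm &
    radii <= inner_radius_mm + peak_search_mm
  if (!any(in_search)) return(none)
  ## first radius reaching the (noise-tolerant) maximum: on plateau
  ## profiles (adjacent tissue) the peak is the plateau onset, not the
  ## end of the search window
  hs <- hu[in_search]
  ipk <- which(in_search)[which(hs >= max(hs) - peak_tol_hu)[1]]
  r_peak <- radii[ipk]
  b <- ifelse(radii < r_peak, hu_air, hu_parenchyma)
  ## the clip keeps gross outliers from dominating while staying
  ## symmetric around both baselines, so zero-mean image noise does not
  ## rectify into a thickness bias (a hard [0, 1] clip would)
  integrand <- clamp((hu - b) / (hu_wall_ref - b), -0.25, 1.25)
  win <- radii >= inner_radius_mm - window_mm & radii <= r_peak + window_mm
  integrand[!win | !is.finite(integrand)] <- 0
  thickness <- step * sum(integrand)
  if (!details) return(thickness)
  center <- if (thickness > 0) sum(radii * integrand) / sum(integrand) else
    NA_real_
  list(thickness_mm = thickness, r_peak_mm = r_peak, center_mm = center)
}

#' Outer-border detectability of a radial profile
#'
#' TRUE when the profile falls below
#' `hu_parenchyma + f_out * (hu_wall_ref - hu_parenchyma)` within
#' `d_max_mm` beyond the wall peak — i.e. no adjacent tissue of
#' wall-like density hides the outer border.
#'
#' @inheritParams measure_wall_ibwt
#' @param r_peak_mm Wall peak radius, mm.
#' @param f_out Descent fraction toward parenchyma (default 0.5).
#' @param d_max_mm Search window beyond the peak, mm.
#' @return Logical.
#' @export
assess_outer_border <- function(radii, hu, r_peak_mm, hu_parenchyma,
                                hu_wall_ref, f_out = 0.5, d_max_mm = 2) {
  if (is.na(r_peak_mm) || d_max_mm <= 0) return(FALSE)
  thresh <- hu_parenchyma + f_out * (hu_wall_ref - hu_parenchyma)
  sel <- radii > r_peak_mm & radii <= r_peak_mm + d_max_mm
  if (!any(sel)) return(FALSE)
  any(hu[sel] < thresh, na.rm = TRUE)
}

## wall-peak radius used by the outer assessment (same search as the
## thickness integral)
wall_peak_radius <- function(radii, hu, inner_radius_mm,
                             peak_search_mm = 2) {
  if (is.na(inner_radius_mm)) return(NA_real_)
  in_search <- radii > inner_radius_mm &
    radii <= inner_radius_mm + peak_search_mm
  if (!any(in_search)) return(NA_real_)
  hs <- hu[in_search]
  radii[which(in_search)[which(hs >= max(hs) - 25)[1]]]
}

#' Summarize one cross-section into a location measurement
#'
#' Per ray: inner border (half of the ray's own peak above lumen air),
#' wall thickness (HU integral against the configured wall reference
#' density), and outer-border detectability. The internal diameter is
#' twice the mean inner radius over rays with an inner border (an
#' elliptical lumen therefore gives the mean-radius diameter, not the
#' equal-area one); AWT averages assessed rays only; APF is the assessed
#' fraction of rays.
#'
#' @param cs A `cross_section`.
#' @param config A [ct_config()] list.
#' @return A one-row data.frame (branch_id, generation, lobe,
#'   position_mm, internal_diameter_mm, awt_mm, apf_local, n_rays), or
#'   NULL when fewer than half of the rays have an inner border.
#' @export
summarize_cross_section <- function(cs, config = ct_config()) {
  nr <- cs$n_rays
  radii <- cs$radii
  hu_air <- median(cs$hu[, 1], na.rm = TRUE)
  inner <- rep(NA_real_, nr)
  inner_ref <- rep(NA_real_, nr)
  thick <- rep(NA_real_, nr)
  assessed <- rep(FALSE, nr)
  min_contrast <- 150  # HU; below this a ray has no credible wall signal
  ## light symmetric smoothing: suppresses noise in the border and peak
  ## detections without moving edges or changing the integral
  sm <- cs$hu
  nc <- ncol(sm)
  sm <- (cbind(sm[, 1], sm[, -nc]) + sm + cbind(sm[, -1], sm[, nc])) / 3
  ## section-level baseline/peak estimates: pooling over rays makes them
  ## nearly noise-free, so the thickness integral stays unbiased across
  ## dose levels
  distal <- radii >= max(radii) - 1
  ## pooled parenchyma baseline over rays that actually end in
  ## parenchyma (not in an adjacent tissue plateau or outside the lung)
  ray_par <- apply(sm[, distal, drop = FALSE], 1, median)
  par_ok <- is.finite(ray_par) & ray_par < config$wall_hu_ref - 100
  sec_par <- if (any(par_ok)) {
    median(sm[par_ok, distal], na.rm = TRUE)
  } else NA_real_
  sec_peak <- median(apply(sm, 1, max), na.rm = TRUE)
  ## noise floor of the smoothed profiles, from the flat lumen-air core;
  ## widens the peak-onset tolerance so it is noise-invariant
  air_core <- radii <= 0.8
  sigma_s <- if (sum(air_core) >= 4) {
    median(apply(sm[, air_core, drop = FALSE], 1, stats::mad), na.rm = TRUE)
  } else 0
  peak_tol <- 25 + 2 * sigma_s
  for (k in seq_len(nr)) {
    prof <- sm[k, ]
    if (anyNA(prof)) next  # ray exits the volume: unassessed
    if (max(prof) - hu_air < min_contrast) next
    if (sec_peak - hu_air < min_contrast) next
    inner[k] <- detect_inner_border(radii, prof, hu_air, sec_peak)
    if (is.na(inner[k])) next
    ## ray ends in tissue of near-wall density (adjacent structure or
    ## volume edge): inner border stands, but there is no usable outer
    ## baseline, so the ray is unassessed
    if (!par_ok[k] || is.na(sec_par)) next
    hu_par <- sec_par
    d <- measure_wall_ibwt(radii, prof, inner[k], hu_air,
                           config$wall_hu_ref, hu_par,
                           window_mm = config$window_mm, details = TRUE,
                           peak_tol_hu = peak_tol)
    thick[k] <- d$thickness_mm
    assessed[k] <- assess_outer_border(radii, prof, d$r_peak_mm, hu_par,
                                       sec_peak, f_out = config$f_out,
                                       d_max_mm = config$d_max_mm)
    ## peak-centered inner radius: the half-maximum crossing drifts
    ## inward for sub-voxel walls, but the wall center (integrand
    ## centroid) and the integral thickness are blur-invariant in 1D,
    ## so center - thickness/2 restores the border. For a curved wall
    ## an isotropic PSF additionally folds wall mass inward, shifting
    ## the centroid by about sigma^2 / (2 R); sigma is recovered from
    ## the blurred wall itself via its peak-amplitude/width relation
    ## A = 2 Phi(t / 2 sigma) - 1. Only trusted on assessed rays.
    if (assessed[k] && !is.na(d$center_mm) && d$thickness_mm > 0) {
      b_eff <- (hu_air + hu_par) / 2
      q <- (sec_peak - b_eff) / (config$wall_hu_ref - b_eff)
      curv <- 0
      if (is.finite(q) && q > 0.05 && q < 0.999) {
        sigma_w <- d$thickness_mm / (2 * qnorm((1 + q) / 2))
        curv <- min(0.15, sigma_w^2 / (2 * d$center_mm))
      }
      cand <- d$center_mm - d$thickness_mm / 2 + curv
      if (cand > 0 && abs(cand - inner[k]) < 1) inner_ref[k] <- cand
    }
  }
  n_inner <- sum(!is.na(inner))
  if (n_inner < nr / 2) return(NULL)
  ok <- assessed & !is.na(thick)
  inner_best <- ifelse(is.na(inner_ref), inner, inner_ref)
  data.frame(
    branch_id = cs$branch_id, generation = cs$generation,
    lobe = ifelse(is.na(cs$lobe), NA_character_, cs$lobe),
    position_mm = cs$position_mm,
    internal_diameter_mm = 2 * mean(inner_best, na.rm = TRUE),
    awt_mm = if (any(ok)) mean(thick[ok]) else NA_real_,
    apf_local = sum(ok) / nr, n_rays = nr,
    stringsAsFactors = FALSE
  )
}

#' Keep locations at a fixed internal diameter with sufficient APF
#'
#' @param locations Data.frame of location measurements (one row per
#'   cross-section, as produced by [summarize_cross_section()]).
#' @param target_mm Target internal diameter, mm (default 3.5).
#' @param tol_mm Diameter tolerance, mm (default 0.25).
#' @param min_apf Minimum assessed perimeter fraction (default 0.25).
#' @return Subset of `locations`.
#' @export
select_fixed_diameter_locations <- function(locations, target_mm = 3.5,
                                            tol_mm = 0.25, min_apf = 0.25) {
  if (tol_mm < 0) stop_domain("tol_mm must be non-negative")
  if (nrow(locations) == 0) return(locations)
  keep <- abs(locations$internal_diameter_mm - target_mm) <= tol_mm &
    locations$apf_local >= min_apf & !is.na(locations$awt_mm)
  locations[keep, , drop = FALSE]
}

#' Internal diameter equivalent of a lumen perimeter
#'
#' The 10 mm internal perimeter of the pi10 convention corresponds to
#' about 3.2 mm internal diameter.
#'
#' @param perimeter_mm Internal lumen perimeter, mm.
#' @return Diameter in mm (`perimeter / pi`).
#' @examples
#' perimeter_to_diameter(10)  # ~3.18 mm
#' @export
perimeter_to_diameter <- function(perimeter_mm) {
  if (any(perimeter_mm < 0)) stop_domain("perimeter must be non-negative")
  perimeter_mm / pi
}

#' APF-weighted aggregation of locations to lobes and whole lung
#'
#' Within a lobe, AWT is the APF-weighted mean over locations and the
#' cumulative APF the sum of local APFs; the whole-lung AWT is the
#' APF-weighted mean of the five lobe values,
#' `sum(awt_lobe * apf_lobe) / sum(apf_lobe)`.
#'
#' @param locations Data.frame of retained location measurements with
#'   `lobe`, `awt_mm`, `apf_local`.
#' @return List with `lobes` (one row per lobe: awt_mm, apf_cum,
#'   n_locations), `awt_mm` (whole lung), `apf_total`.
#' @export
aggregate_lobes <- function(locations) {
  locations <- locations[!is.na(locations$awt_mm) & !is.na(locations$lobe), ,
                         drop = FALSE]
  if (nrow(locations) == 0) stop_domain("no retained locations to aggregate")
  sp <- split(locations, locations$lobe)
  lobes <- do.call(rbind, lapply(names(sp), function(lb) {
    d <- sp[[lb]]
    w <- sum(d$apf_local)
    data.frame(lobe = lb,
               awt_mm = if (w > 0) sum(d$awt_mm * d$apf_local) / w else
                 NA_real_,
               apf_cum = w, n_locations = nrow(d),
               stringsAsFactors = FALSE)
  }))
  wtot <- sum(lobes$apf_cum)
  if (wtot <= 0) stop_domain("zero total APF: whole-lung AWT undefined")
  list(lobes = lobes,
       awt_mm = sum(lobes$awt_mm * lobes$apf_cum) / wtot,
       apf_total = wtot)
}

#' Generation of a measurement location
#'
#' Topological depth (from the trachea root) of the branch a location
#' belongs to.
#'
#' @param location One location row (with `branch_id`).
#' @param tree An `airway_tree` or a list of `centerline` objects.
#' @return Integer generation.
#' @export
generation_of_location <- function(location, tree) {
  if (inherits(tree, "airway_tree")) {
    ids <- vapply(tree$branches, function(b) b$branch_id, numeric(1))
    gens <- vapply(tree$branches, function(b) b$generation, numeric(1))
  } else {
    ids <- vapply(tree, function(b) b$branch_id, numeric(1))
    gens <- vapply(tree, function(b) b$generation, numeric(1))
  }
  i <- match(location$branch_id, ids)
  if (is.na(i)) stop_domain("location branch ", location$branch_id,
                            " is not in the tree")
  as.integer(gens[i])
}

#' Measure all airway locations in a CT volume
#'
#' End-to-end measurement: centerline extraction from the lumen labels
#' (unless centerlines are supplied), lobe assignment, trimming near
#' junctions (perpendicular planes are ill-defined there), perpendicular
#' resampling, and per-location summaries.
#'
#' @param ct A `ct_volume`.
#' @param labels A `label_volume`.
#' @param config A [ct_config()] list.
#' @param centerlines Optional pre-computed `centerline` list (e.g. from
#'   phantom truth); extracted from `labels` when NULL.
#' @return Data.frame of location measurements (all diameters; apply
#'   [select_fixed_diameter_locations()] for a fixed-diameter analysis).
#' @export
measure_airways <- function(ct, labels, config = ct_config(),
                            centerlines = NULL) {
  if (is.null(centerlines)) {
    centerlines <- extract_centerlines(labels)
    centerlines <- assign_lobes(centerlines, labels)
  }
  rows <- list()
  for (cl in centerlines) {
    clt <- trim_centerline(cl, config$trim_mm)
    if (is.null(clt)) next
    secs <- sample_cross_sections(ct, clt, step_mm = config$centerline_step_mm,
                                  n_rays = config$n_rays,
                                  ray_len_mm = config$ray_len_mm,
                                  ray_step_mm = config$ray_step_mm)
    for (cs in secs) {
      r <- summarize_cross_section(cs, config)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
  }
  if (length(rows) == 0) {
    return(data.frame(branch_id = numeric(0), generation = integer(0),
                      lobe = character(0), position_mm = numeric(0),
                      internal_diameter_mm = numeric(0), awt_mm = numeric(0),
                      apf_local = numeric(0), n_rays = integer(0)))
  }
  do.call(rbind, rows)
}

## drop centerline samples near junctions: the proximal end by the parent
## lumen radius (the extracted path cuts through the parent there) plus
## the configured margin, the distal end by the margin plus local radius
trim_centerline <- function(cl, trim_mm = 2) {
  pts <- cl$points
  if (nrow(pts) < 2) return(NULL)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  prox <- trim_mm + max(0, cl$parent_radius_mm %||% 0, na.rm = TRUE)
  dist <- trim_mm + max(0, cl$radius_mm %||% 0, na.rm = TRUE)
  keep <- s >= prox & s <= L - dist
  if (sum(keep) < 2) return(NULL)
  cl$points <- pts[keep, , drop = FALSE]
  cl$tangents <- cl$tangents[keep, , drop = FALSE]
  cl
}

#' Subject-level imaging metrics
#'
#' Combines the fixed-diameter airway measurement (APF-weighted across
#' lobes) with densitometry into one record.
#'
#' @param ct,labels Volumes.
#' @param config A [ct_config()] list.
#' @param centerlines Optional `centerline` list.
#' @return List with `awt35_mm`, `apf_total`, `lobes`, `n_locations`,
#'   `perc15_hu`, `laa950_pct`, `log_laa950`, `lung_volume_l`,
#'   `calibration_shift_hu`.
#' @export
subject_metrics <- function(ct, labels, config = ct_config(),
                            centerlines = NULL) {
  ## recalibrate once so both the wall integral (fixed soft-tissue
  ## reference) and the densitometry see drift-free HU
  rc <- recalibrate_hu(ct, labels)
  ct <- rc$ct
  locs <- measure_airways(ct, labels, config, centerlines)
  sel <- select_fixed_diameter_locations(locs, config$target_diameter_mm,
                                         config$tol_mm, config$min_apf)
  agg <- if (nrow(sel) > 0) aggregate_lobes(sel) else
    list(lobes = NULL, awt_mm = NA_real_, apf_total = 0)
  dens <- quantify_densitometry(ct, labels, config, recalibrate = FALSE)
  list(awt35_mm = agg$awt_mm, apf_total = agg$apf_total, lobes = agg$lobes,
       n_locations = nrow(sel), perc15_hu = dens$perc15_hu,
       laa950_pct = dens$laa950_pct, log_laa950 = dens$log_laa950,
       lung_volume_l = dens$lung_volume_l,
       calibration_shift_hu = rc$calibration_shift_hu)
}
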