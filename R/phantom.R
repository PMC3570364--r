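## Digital CT phantoms: airway trees of known lumen diameter and wall
## thickness embedded in parenchyma with a controllable low-attenuation
## fraction, imaged at the screening-protocol geometry (Gaussian in-plane
## PSF for the soft kernel, boxcar slice profile, additive noise).
##
## Default tissue densities: lumen/trachea air -1000 HU, airway wall 0 HU,
## parenchyma -880 HU, emphysematous tissue -980 HU. These are physiologic
## choices consistent with the -950 HU low-attenuation threshold; the
## phantom, not a scanner, defines them.

#' Construct an airway tree from explicit branches
#'
#' Each branch is a straight segment. Generations are topological:
#' trachea root = 0, each child one more than its parent.
#'
#' @param branches List of branches; each a list with fields `branch_id`,
#'   `parent_id` (NA for a root), `lobe` (one of LUL, LLL, RUL, RML, RLL,
#'   or NA for trachea/main bronchi), `generation`, `p0`, `p1` (3-vectors,
#'   world mm), `lumen_diameter_mm`, `wall_thickness_mm`, and optionally
#'   `wall_hu` (default 0), `vessel_fraction` (default 0),
#'   `vessel_thickness_mm`, `vessel_angle0`.
#' @return An `airway_tree` object.
#' @export
airway_tree <- function(branches) {
  branches <- lapply(branches, function(b) {
    b$wall_hu <- b$wall_hu %||% 0
    b$vessel_fraction <- b$vessel_fraction %||% 0
    b$vessel_thickness_mm <- b$vessel_thickness_mm %||% 3
    b$vessel_angle0 <- b$vessel_angle0 %||% 0
    b$adjacent_vessel <- b$vessel_fraction > 0
    if (b$lumen_diameter_mm <= 0) stop_domain("lumen_diameter_mm must be > 0")
    if (b$wall_thickness_mm <= 0) stop_domain("wall_thickness_mm must be > 0")
    b
  })
  ids <- vapply(branches, function(b) b$branch_id, numeric(1))
  for (b in branches) {
    if (!is.na(b$parent_id)) {
      p <- branches[[match(b$parent_id, ids)]]
      if (b$generation != p$generation + 1L) {
        stop_domain("generation(child) must equal generation(parent) + 1")
      }
    }
  }
  structure(list(branches = branches), class = "airway_tree")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.airway_tree <- function(x, ...) {
  tt <- as.data.frame(x)
  cat(sprintf("<airway_tree> %d branches, generations %d-%d\n",
              nrow(tt), min(tt$generation), max(tt$generation)))
  invisible(x)
}

#' Ground-truth table of an airway tree
#'
#' @param x An `airway_tree`.
#' @param ... Unused.
#' @return One row per branch: ids, lobe, generation, lumen diameter,
#'   wall thickness, length.
#' @export
as.data.frame.airway_tree <- function(x, ...) {
  do.call(rbind, lapply(x$branches, function(b) {
    data.frame(branch_id = b$branch_id, parent_id = b$parent_id,
               lobe = ifelse(is.na(b$lobe), NA_character_, b$lobe),
               generation = b$generation,
               lumen_diameter_mm = b$lumen_diameter_mm,
               wall_thickness_mm = b$wall_thickness_mm,
               length_mm = sqrt(sum((b$p1 - b$p0)^2)),
               adjacent_vessel = b$vessel_fraction > 0,
               stringsAsFactors = FALSE)
  }))
}

#' Single straight tube phantom tree
#'
#' @param lumen_diameter_mm,wall_thickness_mm Tube dimensions, mm.
#' @param length_mm Tube length, mm.
#' @param lobe Lobe code the tube is assigned to.
#' @param axis Unit direction of the tube (default along z).
#' @param origin Start point, world mm.
#' @return An `airway_tree` with one generation-1 branch.
#' @export
single_tube_tree <- function(lumen_diameter_mm = 3.5, wall_thickness_mm = 0.6,
                             length_mm = 25, lobe = "RUL",
                             axis = c(0, 0, 1), origin = c(0, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  airway_tree(list(list(
    branch_id = 1, parent_id = NA, lobe = lobe, generation = 1L,
    p0 = origin, p1 = origin + length_mm * axis,
    lumen_diameter_mm = lumen_diameter_mm,
    wall_thickness_mm = wall_thickness_mm
  )))
}

rotate_about <- function(v, axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  v * cos(theta) + pracma_cross(axis, v) * sin(theta) +
    axis * sum(axis * v) * (1 - cos(theta))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build a rooted bifurcating airway tree spanning five lobes
#'
#' The trachea (generation 0) descends into left/right main bronchi, then
#' lobar bronchi for LUL, LLL, RUL, RML, RLL; each lobar bronchus carries
#' a binary subtree down to the last generation of the diameter map.
#' Diameters are assigned per generation and must be strictly decreasing.
#'
#' @param template `"five_lobe"` or `"single"` (degenerate single tube).
#' @param per_generation_diameters Numeric vector of lumen diameters (mm)
#'   for generations `0..length-1`, strictly decreasing. The default puts
#'   most peripheral branch length in the 3.25-3.75 mm diameter class.
#' @param wall_fraction Wall thickness as a fraction of lumen diameter.
#' @param branch_length_mm Branch length (mm) per generation; recycled at
#'   the last value for deeper generations.
#' @param branching_angle_deg Half-angle between sibling branches.
#' @param jitter_deg Small random perturbation of branch directions.
#' @param seed Integer seed; identical parameters and seed give an
#'   identical tree.
#' @return An `airway_tree`.
#' @export
build_airway_tree <- function(template = c("five_lobe", "single"),
                              per_generation_diameters =
                                c(16, 11, 7.5, 4.9, 3.6, 2.6),
                              wall_fraction = 0.16,
                              branch_length_mm = c(45, 30, 22, 16, 14, 6),
                              branching_angle_deg = 32,
                              jitter_deg = 4,
                              seed = 1L) {
  template <- match.arg(template)
  d <- as.numeric(per_generation_diameters)
  if (any(diff(d) >= 0)) {
    stop_domain("per_generation_diameters must be strictly decreasing")
  }
  if (wall_fraction <= 0 || wall_fraction >= 1) {
    stop_domain("wall_fraction must be in (0, 1)")
  }
  if (template == "single") {
    dd <- d[length(d)]
    return(single_tube_tree(lumen_diameter_mm = dd,
                            wall_thickness_mm = wall_fraction * dd))
  }
  max_gen <- length(d) - 1L
  len_of <- function(g) branch_length_mm[min(g + 1L, length(branch_length_mm))]
  with_seed(seed, {
    branches <- list()
    nid <- 0L
    add <- function(parent_id, lobe, gen, p0, dir) {
      nid <<- nid + 1L
      dir <- dir / sqrt(sum(dir^2))
      b <- list(branch_id = nid, parent_id = parent_id, lobe = lobe,
                generation = gen, p0 = p0, p1 = p0 + len_of(gen) * dir,
                lumen_diameter_mm = d[gen + 1L],
                wall_thickness_mm = wall_fraction * d[gen + 1L],
                dir = dir)
      branches[[nid]] <<- b
      nid
    }
    jitter <- function(dir) {
      if (jitter_deg <= 0) return(dir)
      ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      u <- pracma_cross(dir, ref); u <- u / sqrt(sum(u^2))
      th <- runif(1, -1, 1) * jitter_deg * pi / 180
      ph <- runif(1, 0, 2 * pi)
      ax <- rotate_about(u, dir, ph)
      rotate_about(dir, ax, th)
    }
    grow <- function(parent_idx) {
      p <- branches[[parent_idx]]
      if (p$generation >= max_gen) return(invisible(NULL))
      ref <- if (abs(p$dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      u <- pracma_cross(p$dir, ref); u <- u / sqrt(sum(u^2))
      ## rotate the bifurcation plane per node so the subtree fills 3D
      ax <- rotate_about(u, p$dir, runif(1, 0, 2 * pi))
      th <- branching_angle_deg * pi / 180
      for (s in c(-1, 1)) {
        cid <- add(p$branch_id, p$lobe, p$generation + 1L, p$p1,
                   jitter(rotate_about(p$dir, ax, s * th)))
        grow(cid)
      }
    }
    tr <- add(NA, NA, 0L, c(0, 0, 0), c(0, 0, -1))
    carina <- branches[[tr]]$p1
    lm <- add(tr, NA, 1L, carina, c(-sin(0.6), 0.05, -cos(0.6)))
    rm <- add(tr, NA, 1L, carina, c(sin(0.6), -0.05, -cos(0.6)))
    lend <- branches[[lm]]$p1; rend <- branches[[rm]]$p1
    heads <- c(
      add(lm, "LUL", 2L, lend, c(-0.65, 0.25, 0.45)),
      add(lm, "LLL", 2L, lend, c(-0.45, -0.20, -0.85)),
      add(rm, "RUL", 2L, rend, c(0.65, 0.25, 0.50))
    )
    bi <- add(rm, "RLL", 2L, rend, c(0.30, -0.10, -0.95))  # intermedius
    heads <- c(heads,
               add(bi, "RML", 3L, branches[[bi]]$p1, c(0.60, 0.45, -0.25)),
               add(bi, "RLL", 3L, branches[[bi]]$p1, c(0.25, -0.40, -0.88)))
    for (h in heads) grow(h)
    grow(bi)
    branches <- lapply(branches, function(b) { b$dir <- NULL; b })
    airway_tree(branches)
  })
}

#' Attach an adjacent same-density structure to a branch
#'
#' Paints tissue of airway-wall density over an angular sector of the
#' branch's outer perimeter, emulating a blood vessel abutting the wall;
#' the outer border is then undetectable on rays through that sector.
#'
#' @param tree An `airway_tree`.
#' @param branch_id Branch to occlude.
#' @param fraction Fraction of the perimeter covered, in (0, 1).
#' @param thickness_mm Radial extent of the adjacent tissue, mm.
#' @param angle0 Start angle of the sector, radians.
#' @return The modified tree.
#' @export
attach_vessel <- function(tree, branch_id, fraction, thickness_mm = 3,
                          angle0 = 0) {
  stopifnot(fraction > 0, fraction < 1)
  ids <- vapply(tree$branches, function(b) b$branch_id, numeric(1))
  i <- match(branch_id, ids)
  if (is.na(i)) stop_domain("no such branch: ", branch_id)
  tree$branches[[i]]$vessel_fraction <- fraction
  tree$branches[[i]]$vessel_thickness_mm <- thickness_mm
  tree$branches[[i]]$vessel_angle0 <- angle0
  tree$branches[[i]]$adjacent_vessel <- TRUE
  tree
}

#' Phantom tissue truth
#'
#' Scalar ground truth for densitometry: parenchymal density (with a
#' Gaussian texture), fraction of lung voxels replaced by low-attenuation
#' emphysema blobs, and a deliberate whole-scan calibration drift.
#'
#' @param parenchyma_hu Mean parenchymal density, HU.
#' @param parenchyma_sd_hu Parenchymal texture standard deviation, HU.
#' @param emphysema_fraction Target fraction of lung voxels assigned the
#'   emphysema density, in `[0, 1]`.
#' @param emphysema_hu Mean emphysema density, HU (must be < -950 when
#'   `emphysema_fraction > 0`).
#' @param emphysema_sd_hu Emphysema texture standard deviation, HU.
#' @param trachea_offset_hu Calibration drift added to the whole volume.
#' @param blob_radius_mm Range of emphysema blob radii, mm.
#' @param seed Integer seed for texture and blob placement.
#' @return A `phantom_truth` object.
#' @export
phantom_truth <- function(parenchyma_hu = -880, parenchyma_sd_hu = 20,
                          emphysema_fraction = 0, emphysema_hu = -980,
                          emphysema_sd_hu = 10, trachea_offset_hu = 0,
                          blob_radius_mm = c(2, 6), seed = 1L) {
  if (emphysema_fraction < 0 || emphysema_fraction > 1) {
    stop_domain("emphysema_fraction must be in [0, 1]")
  }
  if (emphysema_fraction > 0 && emphysema_hu >= -950) {
    stop_domain("emphysema_hu must be below -950 HU")
  }
  structure(
    list(parenchyma_hu = parenchyma_hu, parenchyma_sd_hu = parenchyma_sd_hu,
         emphysema_fraction = emphysema_fraction, emphysema_hu = emphysema_hu,
         emphysema_sd_hu = emphysema_sd_hu,
         trachea_offset_hu = trachea_offset_hu,
         blob_radius_mm = blob_radius_mm, seed = as.integer(seed)),
    class = "phantom_truth"
  )
}

## distance from points (n x 3) to segment p0-p1, plus angular coordinate
## about the segment axis
dist_to_segment <- function(pts, p0, p1) {
  ax <- p1 - p0
  L <- sqrt(sum(ax^2))
  u <- ax / L
  w <- sweep(pts, 2, p0, "-")
  t <- clamp(w %*% u, 0, L)
  dvec <- w - tcrossprod(t, u)
  list(d = sqrt(rowSums(dvec^2)), t = as.numeric(t), dvec = dvec, u = u)
}

## orthonormal in-plane frame for a direction
plane_frame <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  a <- pracma_cross(u, ref); a <- a / sqrt(sum(a^2))
  b <- pracma_cross(u, a)
  list(u = a, v = b)
}

## voxel-subgrid indices covering a world-space bounding box
subgrid <- function(coords, lo, hi) {
  lapply(1:3, function(k) {
    which(coords[[k]] >= lo[k] & coords[[k]] <= hi[k])
  })
}

#' Rasterize an airway-tree phantom to CT and label volumes
#'
#' Paints parenchyma (with lobe labels), emphysema blobs, airway walls and
#' lumens into a clean HU grid, then applies the acquisition model:
#' global calibration drift, in-plane Gaussian PSF, slice-profile
#' averaging, and additive Gaussian noise. Labels are untouched by blur
#' and noise.
#'
#' The lung is either a margin envelope around all lobar branches
#' (`lung = list(type = "envelope", margin_mm = 8)`) or an explicit
#' ellipsoid (`lung = list(type = "ellipsoid", center =, semiaxes =,
#' lobe = "RUL")`) with analytically known volume.
#'
#' @param tree An `airway_tree`.
#' @param truth A `phantom_truth`.
#' @param acq An `acquisition_spec`.
#' @param lung Lung-region specification, see Details.
#' @param z_margin_mm Extra volume margin beyond the tree along z, mm.
#' @param keep_clean Keep the pre-blur, pre-noise volume in the result.
#' @return List with `ct` (a `ct_volume`), `labels` (a `label_volume`),
#'   and `truth` augmented with `truth_perc15_hu`,
#'   `emphysema_voxel_fraction`, `lung_voxel_count` and
#'   `background_hu`; plus `clean` when requested.
#' @export
rasterize_phantom <- function(tree, truth, acq,
                              lung = list(type = "envelope", margin_mm = 8),
                              z_margin_mm = 6, keep_clean = FALSE) {
  legend <- label_legend()
  branches <- tree$branches
  dx <- acq$fov_mm / acq$matrix
  dz <- acq$slice_increment_mm
  ## bounding box of the tree plus wall and lung margin
  r_out <- vapply(branches, function(b) {
    b$lumen_diameter_mm / 2 + b$wall_thickness_mm +
      if (b$vessel_fraction > 0) b$vessel_thickness_mm else 0
  }, numeric(1))
  margin <- if (identical(lung$type, "envelope")) lung$margin_mm %||% 8 else 2
  pmat <- do.call(rbind, lapply(branches, function(b) rbind(b$p0, b$p1)))
  pad <- max(r_out) + margin + 2
  lo <- apply(pmat, 2, min) - pad
  hi <- apply(pmat, 2, max) + pad
  if (identical(lung$type, "ellipsoid")) {
    lo <- pmin(lo, lung$center - lung$semiaxes - 2)
    hi <- pmax(hi, lung$center + lung$semiaxes + 2)
  }
  if (hi[1] - lo[1] > acq$fov_mm || hi[2] - lo[2] > acq$fov_mm) {
    wid <- vapply(branches, function(b) max(abs(c(b$p0[1:2], b$p1[1:2]))),
                  numeric(1))
    stop_domain("tree does not fit in the field of view (widest branch: ",
                branches[[which.max(wid)]]$branch_id, ")")
  }
  nx <- acq$matrix
  ny <- acq$matrix
  nz <- as.integer(ceiling((hi[3] - lo[3] + 2 * z_margin_mm) / dz)) + 1L
  ctr <- (lo + hi) / 2
  origin <- c(ctr[1] - (nx - 1) / 2 * dx, ctr[2] - (ny - 1) / 2 * dx,
              lo[3] - z_margin_mm)
  coords <- list(origin[1] + (seq_len(nx) - 1) * dx,
                 origin[2] + (seq_len(ny) - 1) * dx,
                 origin[3] + (seq_len(nz) - 1) * dz)
  dims <- c(nx, ny, nz)
  background_hu <- 40  # soft-tissue body background
  clean <- array(background_hu, dims)
  labels <- array(legend[["outside"]], dims)
  wall_mask <- array(FALSE, dims)

  ## partial-volume coverage of a disc of radius r at voxel distance d:
  ## linear ramp over one in-plane voxel, so the rasterized annulus mass
  ## matches the geometric one (binary painting would inflate thin walls)
  coverage <- function(d, r) clamp((r + dx / 2 - d) / dx, 0, 1)

  paint <- function(b, what) {
    rl <- b$lumen_diameter_mm / 2
    rw <- rl + b$wall_thickness_mm
    rv <- rw + if (b$vessel_fraction > 0) b$vessel_thickness_mm else 0
    rad <- switch(what, envelope = rw + margin, wall = rv, lumen = rl)
    blo <- pmin(b$p0, b$p1) - rad - dx
    bhi <- pmax(b$p0, b$p1) + rad + dx
    sg <- subgrid(coords, blo, bhi)
    if (any(lengths(sg) == 0)) return(invisible(NULL))
    pts <- as.matrix(expand.grid(coords[[1]][sg[[1]]], coords[[2]][sg[[2]]],
                                 coords[[3]][sg[[3]]]))
    ds <- dist_to_segment(pts, b$p0, b$p1)
    ii <- as.matrix(expand.grid(sg[[1]], sg[[2]], sg[[3]]))
    if (what == "envelope") {
      sel <- ds$d <= rw + margin
      idx <- ii[sel, , drop = FALSE]
      keep <- labels[idx] == legend[["outside"]]
      labels[idx[keep, , drop = FALSE]] <<- legend[[b$lobe]]
    } else if (what == "wall") {
      w <- coverage(ds$d, rw)
      if (b$vessel_fraction > 0) {
        fr <- plane_frame(ds$u)
        ang <- atan2(ds$dvec %*% fr$v, ds$dvec %*% fr$u) %% (2 * pi)
        rel <- (ang - b$vessel_angle0 %% (2 * pi)) %% (2 * pi)
        insec <- rel <= b$vessel_fraction * 2 * pi
        w2 <- coverage(ds$d, rv)
        w[insec] <- w2[insec]
      }
      sel <- w > 0
      idx <- ii[sel, , drop = FALSE]
      clean[idx] <<- (1 - w[sel]) * clean[idx] + w[sel] * b$wall_hu
      wall_mask[idx[w[sel] > 0.5, , drop = FALSE]] <<- TRUE
    } else {
      w <- coverage(ds$d, rl)
      sel <- w > 0
      idx <- ii[sel, , drop = FALSE]
      clean[idx] <<- (1 - w[sel]) * clean[idx] + w[sel] * (-1000)
      bin <- ds$d <= rl
      idxb <- ii[bin, , drop = FALSE]
      labels[idxb] <<- if (b$generation == 0L) legend[["trachea"]] else
        legend[["airway_lumen"]]
      wall_mask[idxb] <<- FALSE
    }
    invisible(NULL)
  }

  ## lung region with lobe labels
  if (identical(lung$type, "ellipsoid")) {
    e <- sweep(as.matrix(expand.grid(coords[[1]], coords[[2]], coords[[3]])),
               2, lung$center, "-")
    inside <- rowSums(sweep(e, 2, lung$semiaxes, "/")^2) <= 1
    labels[array(inside, dims)] <- legend[[lung$lobe %||% "RUL"]]
  } else {
    for (b in branches) if (!is.na(b$lobe)) paint(b, "envelope")
  }

  ## parenchymal texture and emphysema blobs first; airway walls and
  ## lumens are then blended over them with partial-volume coverage
  lung_mask <- labels >= legend[["LUL"]] & labels <= legend[["RLL"]]
  paren <- lung_mask
  n_par <- sum(paren)
  emph_mask <- array(FALSE, dims)
  with_seed(truth$seed, {
    ## textures are kept clear of the -950 HU threshold so the phantom's
    ## low-attenuation area is exactly its emphysema voxel set
    clean[paren] <- pmax(rnorm(n_par, truth$parenchyma_hu,
                               truth$parenchyma_sd_hu), -945)
    if (truth$emphysema_fraction > 0 && n_par > 0) {
      target <- round(truth$emphysema_fraction * sum(lung_mask))
      cand <- which(paren)
      ai <- arrayInd(cand, dims)
      cw <- cbind(coords[[1]][ai[, 1]], coords[[2]][ai[, 2]],
                  coords[[3]][ai[, 3]])
      got <- 0L
      guard <- 0L
      blob_log <- numeric(0)
      while (got < target && guard < 10000L) {
        guard <- guard + 1L
        ci <- sample.int(length(cand), 1)
        r <- runif(1, truth$blob_radius_mm[1], truth$blob_radius_mm[2])
        blob_log <- c(blob_log, r)
        inblob <- which(rowSums(sweep(cw, 2, cw[ci, ], "-")^2) <= r^2)
        new <- inblob[!emph_mask[cand[inblob]]]
        if (length(new) + got > target) {
          new <- new[sample.int(length(new), target - got)]
        }
        emph_mask[cand[new]] <- TRUE
        got <- got + length(new)
      }
      clean[emph_mask] <- pmin(rnorm(sum(emph_mask), truth$emphysema_hu,
                                     truth$emphysema_sd_hu), -955)
      truth$blob_radii_mm <- blob_log
    }
  })
  for (b in branches) paint(b, "wall")
  for (b in branches) paint(b, "lumen")
  lung_mask <- labels >= legend[["LUL"]] & labels <= legend[["RLL"]]
  emph_mask <- emph_mask & lung_mask & !wall_mask

  lab_vol <- label_volume(labels, c(dx, dx, dz), origin)
  ## ground-truth densitometry from the clean, drift-free mix
  clean_vol <- ct_volume(clamp(clean, -1024, 3071), c(dx, dx, dz), origin)
  dens_mask <- lung_mask_excluding_airways(lab_vol)
  truth$truth_perc15_hu <- if (sum(dens_mask) >= 100) {
    as.numeric(quantile(clean_vol$voxels[dens_mask], 0.15, type = 7))
  } else NA_real_
  truth$emphysema_voxel_fraction <-
    if (sum(lung_mask) > 0) sum(emph_mask) / sum(lung_mask) else 0
  truth$lung_voxel_count <- sum(lung_mask)
  truth$background_hu <- background_hu
  if (identical(lung$type, "ellipsoid")) {
    truth$lung_geometry <- lung
  }

  ct <- apply_acquisition(clean_vol, acq, truth$trachea_offset_hu)
  out <- list(ct = ct, labels = lab_vol, truth = truth)
  if (keep_clean) out$clean <- clean_vol
  out
}

#' Apply the acquisition model to a clean phantom volume
#'
#' Adds the calibration drift, blurs in-plane with a Gaussian PSF of the
#' specified FWHM, averages along z over the slice thickness, and adds
#' Gaussian noise of the specified SD (seeded). Simulated HU are not
#' quantized or clipped: clipping noise at the storage floor (-1024)
#' would destroy the exact linearity in the calibration drift that
#' trachea recalibration relies on.
#'
#' @param clean_vol A `ct_volume` of clean HU values.
#' @param acq An `acquisition_spec`.
#' @param offset_hu Global calibration drift, HU.
#' @return A `ct_volume`.
#' @export
apply_acquisition <- function(clean_vol, acq, offset_hu = 0) {
  v <- clean_vol$voxels + offset_hu
  sig <- fwhm_to_sigma(acq$psf_fwhm_mm)
  kx <- gaussian_kernel(sig / clean_vol$spacing_mm[1])
  ky <- gaussian_kernel(sig / clean_vol$spacing_mm[2])
  kz <- boxcar_kernel(acq$slice_thickness_mm / clean_vol$spacing_mm[3])
  if (length(kx) > 1) v <- convolve_axis(v, kx, 1L)
  if (length(ky) > 1) v <- convolve_axis(v, ky, 2L)
  if (length(kz) > 1) v <- convolve_axis(v, kz, 3L)
  if (acq$noise_sd_hu > 0) {
    v <- v + with_seed(acq$seed, array(rnorm(length(v), 0, acq$noise_sd_hu),
                                       dim(v)))
  }
  ct_volume(v, clean_vol$spacing_mm, clean_vol$origin_mm)
}

#' Rasterize the same scene at two dose levels
#'
#' The two volumes share geometry and blur and differ only in the noise
#' realization/scale (low dose noisier than or equal to high dose).
#'
#' @param tree,truth,lung As in [rasterize_phantom()].
#' @param acq_low,acq_high Acquisition specs; identical geometry required.
#' @return List with `ct_low`, `ct_high`, `labels`, `truth`.
#' @export
generate_dose_pair <- function(tree, truth, acq_low, acq_high,
                               lung = list(type = "envelope", margin_mm = 8)) {
  geom <- c("fov_mm", "matrix", "slice_thickness_mm", "slice_increment_mm",
            "psf_fwhm_mm")
  if (!isTRUE(all.equal(acq_low[geom], acq_high[geom]))) {
    stop_domain("dose pair must share acquisition geometry")
  }
  if (acq_low$noise_sd_hu < acq_high$noise_sd_hu) {
    stop_domain("low-dose noise must be >= high-dose noise")
  }
  ras <- rasterize_phantom(tree, truth, acq_low, lung = lung,
                           keep_clean = TRUE)
  ct_high <- apply_acquisition(ras$clean, acq_high,
                               truth$trachea_offset_hu)
  list(ct_low = ras$ct, ct_high = ct_high, labels = ras$labels,
       truth = ras$truth)
}
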