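## Airway centerline extraction from a lumen label mask.
##
## The lumen voxel graph (26-connectivity, Euclidean edge weights) is
## decomposed by iterative farthest-point geodesic paths from the trachea
## root: each new branch is the shortest path from the voxel farthest
## from the current skeleton back to it, accepted only when it extends
## well beyond the local lumen radius (so bulges of wide airways do not
## spawn spurious branches). The voxel paths are then split at junctions,
## resampled, and recentred to sub-voxel accuracy by perpendicular-slab
## centroids of the lumen.

neighbor_offsets26 <- function() {
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  g <- g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
  ## keep one of each +/- pair
  keep <- g$dk > 0 | (g$dk == 0 & (g$dj > 0 | (g$dj == 0 & g$di > 0)))
  as.matrix(g[keep, ])
}

## graph over mask voxels; returns igraph, per-vertex array indices,
## world coords, and a linear-index lookup
lumen_graph <- function(mask, spacing, origin) {
  dm <- dim(mask)
  lin <- which(mask)
  n <- length(lin)
  if (n == 0) return(NULL)
  id_of <- array(0L, dm)
  id_of[lin] <- seq_len(n)
  ai <- arrayInd(lin, dm)
  offs <- neighbor_offsets26()
  efrom <- integer(0); eto <- integer(0); ew <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    nb <- ai + matrix(o, n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    nid <- rep(0L, n)
    nid[ok] <- id_of[nb[ok, , drop = FALSE]]
    has <- nid > 0L
    efrom <- c(efrom, which(has))
    eto <- c(eto, nid[has])
    ew <- c(ew, rep(sqrt(sum((o * spacing)^2)), sum(has)))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(efrom, eto), weight = ew)
  world <- cbind(origin[1] + (ai[, 1] - 1) * spacing[1],
                 origin[2] + (ai[, 2] - 1) * spacing[2],
                 origin[3] + (ai[, 3] - 1) * spacing[3])
  ## 6-neighbor boundary voxels, for the radius (distance) transform
  interior <- rep(TRUE, n)
  for (axis in 1:3) for (by in c(-1L, 1L)) {
    nb <- ai
    nb[, axis] <- nb[, axis] + by
    ok <- nb[, axis] >= 1 & nb[, axis] <= dm[axis]
    nbid <- rep(0L, n)
    nbid[ok] <- id_of[nb[ok, , drop = FALSE]]
    interior <- interior & nbid > 0L
  }
  list(g = g, ai = ai, world = world, boundary = which(!interior), n = n)
}

## geodesic distance of every mask voxel to a vertex set
dist_to_set <- function(g, n, set) {
  gs <- igraph::add_vertices(g, 1)
  gs <- igraph::add_edges(gs, rbind(n + 1L, set),
                          weight = rep(1e-9, length(set)))
  as.numeric(igraph::distances(gs, v = n + 1L,
                               weights = igraph::E(gs)$weight))[seq_len(n)]
}

#' Extract airway centerlines from a lumen mask
#'
#' @param lumen_mask A `label_volume` (trachea + airway lumen codes are
#'   used) or a logical 3D array (then `spacing_mm`/`origin_mm` must be
#'   given).
#' @param spacing_mm,origin_mm Geometry when `lumen_mask` is a bare array.
#' @param min_branch_mm Minimum geodesic length for a new branch, mm.
#' @param step_mm Resampling step along extracted centerlines, mm.
#' @return List of `centerline` objects, each with `branch_id`,
#'   `parent_id`, `generation` (topological depth; 0 at the trachea root
#'   when a trachea label is present, else 1), `points` (n x 3, world
#'   mm), `tangents` (unit vectors), `radius_mm` (median lumen radius),
#'   `parent_radius_mm`, and `lobe` (NA; see [assign_lobes()]).
#'   An empty mask gives an empty list; a disconnected mask is an error
#'   listing component sizes.
#' @export
extract_centerlines <- function(lumen_mask, spacing_mm = NULL,
                                origin_mm = NULL, min_branch_mm = 3,
                                step_mm = 0.6) {
  has_trachea <- FALSE
  if (inherits(lumen_mask, "label_volume")) {
    has_trachea <- any(lumen_mask$labels == lumen_mask$legend[["trachea"]])
    spacing_mm <- lumen_mask$spacing_mm
    origin_mm <- lumen_mask$origin_mm
    mask <- as_mask(lumen_mask, "lumen")
  } else {
    if (is.null(spacing_mm)) stop_domain("spacing_mm required for bare masks")
    if (is.null(origin_mm)) origin_mm <- c(0, 0, 0)
    mask <- lumen_mask != 0
  }
  lg <- lumen_graph(mask, spacing_mm, origin_mm)
  if (is.null(lg)) return(list())
  comp <- igraph::components(lg$g)
  if (comp$no > 1) {
    stop_domain("lumen mask is disconnected: component sizes ",
                paste(sort(comp$csize, decreasing = TRUE), collapse = ", "))
  }
  dt <- dist_to_set(lg$g, lg$n, lg$boundary) + mean(spacing_mm) / 2
  ## root: most cranial voxel, centred (largest radius on the top slice)
  topz <- max(lg$world[, 3])
  top <- which(lg$world[, 3] > topz - 1.5 * spacing_mm[3])
  root <- top[which.max(dt[top])]

  ## iterative farthest-path skeletonization. Distances and acceptance
  ## thresholds use Euclidean edge lengths; the paths themselves are
  ## routed on centrality weights (length / local radius^2), which pulls
  ## them onto the medial axis instead of letting them hug the wall.
  n <- lg$n
  ends <- igraph::ends(lg$g, igraph::E(lg$g))
  dt_edge <- (dt[ends[, 1]] + dt[ends[, 2]]) / 2
  wcen <- igraph::E(lg$g)$weight / (1 + dt_edge^2)
  gs <- igraph::add_vertices(lg$g, 1)
  super <- n + 1L
  gs <- igraph::add_edges(gs, c(super, root), weight = 1e-9)
  wcen <- c(wcen, 1e-12)
  active <- rep(TRUE, n)
  paths <- list()
  first <- TRUE
  repeat {
    d <- as.numeric(igraph::distances(gs, v = super,
                                      weights = igraph::E(gs)$weight))[seq_len(n)]
    accepted <- FALSE
    repeat {
      cand <- which(active)
      if (length(cand) == 0) break
      far <- cand[which.max(d[cand])]
      if (d[far] < min_branch_mm) break
      sp <- igraph::shortest_paths(gs, from = super, to = far,
                                   weights = wcen)$vpath[[1]]
      vp <- as.integer(sp)[-1]  # drop super; vp[1] = attach vertex
      attach_dt <- dt[vp[1]]
      thresh <- if (first) min_branch_mm else
        max(min_branch_mm, 2 * attach_dt + 1)
      if (d[far] >= thresh) {
        paths[[length(paths) + 1L]] <- vp
        gs <- igraph::add_edges(gs, as.vector(rbind(super, vp)),
                                weight = rep(1e-9, length(vp)))
        wcen <- c(wcen, rep(1e-12, length(vp)))
        active[vp] <- FALSE
        first <- FALSE
        accepted <- TRUE
        break
      }
      ## reject the whole pocket around this candidate
      ball <- rowSums(sweep(lg$world, 2, lg$world[far, ], "-")^2) <=
        (d[far] + mean(spacing_mm))^2
      active[ball] <- FALSE
    }
    if (!accepted) break
  }
  if (length(paths) == 0) paths <- list(root)

  ## skeleton graph: split voxel paths at junction vertices
  verts <- unique(c(root, unlist(paths)))
  vmap <- setNames(seq_along(verts), verts)
  ef <- integer(0); et <- integer(0)
  for (p in paths) {
    if (length(p) > 1) {
      ef <- c(ef, vmap[as.character(p[-length(p)])])
      et <- c(et, vmap[as.character(p[-1])])
    }
  }
  sk <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  if (length(ef)) sk <- igraph::add_edges(sk, rbind(ef, et))
  sk <- igraph::simplify(sk)
  deg <- igraph::degree(sk)
  rootv <- vmap[as.character(root)]
  is_break <- deg != 2
  is_break[rootv] <- TRUE
  ## walk from the root, emitting a branch at each junction/leaf
  branches <- list()
  visited_e <- igraph::as_ids(igraph::E(sk))
  used <- rep(FALSE, igraph::ecount(sk))
  walk <- function(start, parent_branch, gen) {
    for (nb in as.integer(igraph::neighbors(sk, start))) {
      eid <- igraph::get_edge_ids(sk, c(start, nb))
      if (used[eid]) next
      used[eid] <<- TRUE
      seq_v <- c(start, nb)
      cur <- nb
      prev <- start
      while (!is_break[cur]) {
        nxt <- setdiff(as.integer(igraph::neighbors(sk, cur)), prev)
        if (length(nxt) == 0) break
        nxt <- nxt[1]
        eid2 <- igraph::get_edge_ids(sk, c(cur, nxt))
        if (used[eid2]) break
        used[eid2] <<- TRUE
        seq_v <- c(seq_v, nxt)
        prev <- cur
        cur <- nxt
      }
      bid <- length(branches) + 1L
      branches[[bid]] <<- list(id = bid, parent = parent_branch, gen = gen,
                               vseq = verts[seq_v])
      if (is_break[cur]) walk(cur, bid, gen + 1L)
    }
  }
  gen0 <- if (has_trachea) 0L else 1L
  walk(rootv, NA_integer_, gen0)
  if (length(branches) == 0) {
    branches <- list(list(id = 1L, parent = NA_integer_, gen = gen0,
                          vseq = verts))
  }

  ## resample + recentre each branch
  lapply(branches, function(b) {
    pts <- lg$world[b$vseq, , drop = FALSE]
    parent_r <- dt[b$vseq[1]]
    rad <- median(dt[b$vseq])
    cl <- resample_polyline(pts, step_mm)
    cl <- recentre_polyline(cl, lg$world, dt, b$vseq, step_mm)
    tg <- polyline_tangents(cl)
    structure(
      list(branch_id = b$id, parent_id = b$parent, generation = b$gen,
           points = cl, tangents = tg, radius_mm = rad,
           parent_radius_mm = parent_r, lobe = NA_character_,
           length_mm = polyline_length(cl)),
      class = "centerline"
    )
  })
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

resample_polyline <- function(pts, step_mm) {
  if (nrow(pts) < 2) return(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  ns <- max(2L, floor(L / step_mm) + 1L)
  si <- seq(0, L, length.out = ns)
  out <- sapply(1:3, function(k) approx(s, pts[, k], xout = si)$y)
  matrix(out, ncol = 3)
}

polyline_tangents <- function(pts) {
  np <- nrow(pts)
  if (np < 2) return(matrix(c(0, 0, 1), np, 3, byrow = TRUE))
  tg <- rbind(pts[2, ] - pts[1, ],
              if (np > 2) pts[3:np, ] - pts[1:(np - 2), ] else NULL,
              pts[np, ] - pts[np - 1, ])
  tg / sqrt(rowSums(tg^2))
}

## recentre each sample to the centroid of lumen voxels in a thin
## perpendicular slab, then smooth lightly
recentre_polyline <- function(cl, world, dt, vseq, step_mm) {
  np <- nrow(cl)
  if (np < 2) return(cl)
  rloc <- max(dt[vseq])
  ## candidate voxels near this branch only
  lo <- apply(cl, 2, min) - (rloc + 2)
  hi <- apply(cl, 2, max) + (rloc + 2)
  near <- world[, 1] >= lo[1] & world[, 1] <= hi[1] &
    world[, 2] >= lo[2] & world[, 2] <= hi[2] &
    world[, 3] >= lo[3] & world[, 3] <= hi[3]
  w <- world[near, , drop = FALSE]
  if (nrow(w) == 0) return(cl)
  tg <- polyline_tangents(cl)
  out <- cl
  for (i in seq_len(np)) {
    rel <- sweep(w, 2, cl[i, ], "-")
    proj <- rel %*% tg[i, ]
    r2 <- rowSums(rel^2) - proj^2
    sel <- abs(proj) <= 0.6 * step_mm & r2 <= (1.3 * rloc + 1)^2
    if (sum(sel) >= 3) out[i, ] <- colMeans(w[sel, , drop = FALSE])
  }
  ## light running-mean smoothing, endpoints fixed
  if (np > 4) {
    sm <- out
    for (k in 1:3) {
      sm[2:(np - 1), k] <- (out[1:(np - 2), k] + out[2:(np - 1), k] +
                              out[3:np, k]) / 3
    }
    out <- sm
  }
  out
}

#' Assign lobes to extracted centerlines from the label volume
#'
#' Each branch takes the majority lobe code of labeled voxels in a ball
#' around its distal end; branches with no lobe voxels nearby (trachea,
#' main bronchi) keep NA.
#'
#' @param centerlines List of `centerline` objects.
#' @param labels A `label_volume`.
#' @param radius_mm Search-ball radius, mm.
#' @return The centerlines with `lobe` filled in.
#' @export
assign_lobes <- function(centerlines, labels, radius_mm = 6) {
  legend <- labels$legend
  lobes <- lobe_codes(legend)
  dm <- dim(labels$labels)
  lapply(centerlines, function(cl) {
    p <- cl$points[nrow(cl$points), ]
    lo <- floor((p - radius_mm - labels$origin_mm) / labels$spacing_mm) + 1
    hi <- ceiling((p + radius_mm - labels$origin_mm) / labels$spacing_mm) + 1
    lo <- pmax(lo, 1); hi <- pmin(hi, dm)
    if (any(lo > hi)) return(cl)
    sub <- labels$labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    counts <- vapply(lobes, function(code) sum(sub == code), numeric(1))
    if (any(counts > 0)) cl$lobe <- names(lobes)[which.max(counts)]
    cl
  })
}
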