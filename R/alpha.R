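#' Build the alpha (exposed) surface of a pial mesh
#'
#' The alpha surface is the tight outer wrap of the cortex: it follows the
#' pial surface over gyral crowns and bridges sulci whose width is below the
#' scale parameter `alpha`. It is constructed as the boundary of the
#' morphological closing (dilation then erosion by a ball of radius `alpha`)
#' of the pial solid, evaluated on a voxel grid: the exact signed distance to
#' the pial surface is sampled at the grid nodes, combined with a Euclidean
#' distance transform of the dilated set, and the zero level set of
#' `min(signed_distance, alpha - erosion_distance)` is extracted with
#' marching tetrahedra. Where the wrap touches the cortex the field equals
#' the exact signed distance, so contact regions are sub-voxel accurate.
#' The wrap is lightly Taubin-smoothed and locally pushed outward until every
#' pial vertex lies inside it (within `containment_tol`).
#'
#' @param pial a closed [triangle_mesh()].
#' @param alpha wrap scale in mm, or `"auto"` to call [select_alpha()].
#' @param voxel grid spacing in mm; default `vertex_density(pial) / 2`.
#' @param smooth_iters Taubin iterations applied to the raw wrap.
#' @param containment_tol allowed outward protrusion of pial vertices (mm).
#' @return object of class `alpha_surface`: list with `mesh` (the wrap),
#'   `alpha`, `auto_selected`, `voxel`.
#' @export
build_alpha_surface <- function(pial, alpha = "auto", voxel = NULL,
                                smooth_iters = 10L, containment_tol = 0.1) {
  if (!is_closed_mesh(pial))
    stop("build_alpha_surface() requires a closed pial mesh")
  auto <- identical(alpha, "auto")
  if (auto) alpha <- select_alpha(pial)
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be a positive length in mm")
  wrap <- wrap_mesh_at(pial, alpha, voxel = voxel, smooth_iters = smooth_iters)
  wrap <- enforce_containment(wrap$mesh, pial, tol = containment_tol,
                              voxel = wrap$voxel, alpha = alpha)
  structure(list(mesh = wrap$mesh, alpha = alpha, auto_selected = auto,
                 voxel = wrap$voxel),
            class = "alpha_surface")
}

#' @export
print.alpha_surface <- function(x, ...) {
  cat("alpha_surface: alpha =", signif(x$alpha, 4), "mm",
      if (x$auto_selected) "(auto)", "\n")
  print(x$mesh)
  invisible(x)
}

# core wrap construction at a fixed alpha; returns list(mesh, voxel)
wrap_mesh_at <- function(pial, alpha, voxel = NULL, smooth_iters = 10L) {
  dens <- vertex_density(pial)
  # resolution follows the mesh sampling; very large wraps only need to
  # resolve features at the wrap scale
  h <- voxel %||% max(0.75 * dens, alpha / 15)
  bb <- apply(pial$vertices, 2L, range)
  pad <- alpha + 3 * h
  # cap the grid size; coarsen if necessary
  repeat {
    dims <- ceiling((bb[2L, ] - bb[1L, ] + 2 * pad) / h) + 1L
    if (prod(dims) <= 6e6) break
    h <- h * 1.26
  }
  origin <- bb[1L, ] - pad
  # Distance to the pial surface: exact (point-to-triangle) within a few
  # voxels of the surface, where the wrap touches the cortex and sub-voxel
  # accuracy matters; elsewhere approximated by the distance transform of
  # the rasterized surface shell, which is cheap and accurate to ~h.
  shell <- cpp_stamp_triangles(pial$vertices, pial$faces - 1L, origin, h,
                               dims, h)
  edt0 <- cpp_edt3d(shell, dims) * h
  d1 <- edt0 + 0.5 * h        # shell nodes sit up to h off the surface
  near <- which(edt0 <= 2.5 * h)
  ax <- lapply(1:3, function(k) origin[k] + h * (seq_len(dims[k]) - 1L))
  nid <- near - 1L
  npos <- cbind(ax[[1L]][nid %% dims[1L] + 1L],
                ax[[2L]][(nid %/% dims[1L]) %% dims[2L] + 1L],
                ax[[3L]][nid %/% (dims[1L] * dims[2L]) + 1L])
  cd <- closest_distance(npos, pial)
  d1[near] <- as.numeric(cd)
  # sign: flood fill the region farther than one voxel from the surface;
  # nodes near the surface are classified by the nearest face normal
  open <- d1 > h
  ext <- cpp_flood_exterior(open, dims)
  sdist <- d1
  sdist[open & !ext] <- -d1[open & !ext]
  inshell <- !open
  if (any(inshell)) {
    fn <- face_normals(orient_outward(pial))
    sub <- match(which(inshell), near)    # shell nodes all have exact feet
    tri <- attr(cd, "triangle")[sub]
    side <- rowSums((npos[sub, , drop = FALSE] -
                     attr(cd, "foot")[sub, , drop = FALSE]) * fn[tri, , drop = FALSE])
    sdist[inshell] <- ifelse(side >= 0, d1[inshell], -d1[inshell])
  }
  # dilation D = {sdist <= alpha}; erosion distance from D's complement.
  # The node-based EDT overestimates the distance to the continuous region
  # boundary by half a voxel on average; correct for it.
  d2 <- pmax(cpp_edt3d(sdist > alpha, dims) * h - h / 2, 0)
  fld <- pmin(sdist, alpha - d2)
  fld[fld == 0] <- -1e-9
  mt <- cpp_marching_tets(fld, dims, origin, h)
  if (nrow(mt$faces) == 0L)
    stop("alpha wrap is empty at alpha = ", signif(alpha, 4),
         " mm; try a larger alpha")
  wrap <- triangle_mesh(mt$vertices, mt$faces + 1L, name = "alpha", validate = FALSE)
  wrap <- largest_component(wrap)
  wrap <- orient_outward(wrap)
  if (smooth_iters > 0L) wrap <- taubin_smooth(wrap, smooth_iters)
  list(mesh = wrap, voxel = h)
}

largest_component <- function(mesh) {
  comp <- vertex_components(mesh)
  tab <- table(comp)
  if (length(tab) == 1L) return(mesh)
  keepc <- as.integer(names(tab)[which.max(tab)])
  keep <- comp == keepc
  remap <- integer(n_vertices(mesh))
  remap[keep] <- seq_len(sum(keep))
  fkeep <- keep[mesh$faces[, 1L]]
  triangle_mesh(mesh$vertices[keep, , drop = FALSE],
                matrix(remap[mesh$faces[fkeep, ]], ncol = 3L),
                name = mesh$name)
}

n_components <- function(mesh) length(unique(vertex_components(mesh)))

# Contact restoration + containment. Smoothing can draw the wrap slightly
# inside the pial where the two surfaces touch; wrap vertices within one
# voxel of the pial that ended up inside it are snapped back onto the pial
# surface, after which any residual protrusion is below the chordal sag of
# one wrap triangle. A push loop handles whatever remains.
enforce_containment <- function(wrap, pial, tol = 0.1, voxel = NULL, alpha = NULL) {
  h <- voxel %||% vertex_density(pial)
  cdw <- closest_distance(wrap$vertices, pial)
  fnp <- face_normals(orient_outward(pial))
  trip <- attr(cdw, "triangle")
  side_w <- rowSums((wrap$vertices - attr(cdw, "foot")) * fnp[trip, , drop = FALSE])
  snap <- which(side_w < 0 & as.numeric(cdw) < h)
  if (length(snap) > 0L) {
    wrap$vertices[snap, ] <- attr(cdw, "foot")[snap, , drop = FALSE] +
      1e-3 * h * fnp[trip[snap], , drop = FALSE]
  }
  for (it in 1:5) {
    cd <- closest_distance(pial$vertices, wrap)
    fn <- face_normals(wrap)
    tri <- attr(cd, "triangle")
    side <- rowSums((pial$vertices - attr(cd, "foot")) * fn[tri, , drop = FALSE])
    out_dist <- pmin(as.numeric(cd), pmax(side, 0))  # outward component only
    viol <- which(out_dist > tol)
    if (length(viol) == 0L) break
    push <- numeric(n_vertices(wrap))
    for (i in viol) {
      vs <- wrap$faces[tri[i], ]
      push[vs] <- pmax(push[vs], out_dist[i] + 0.1 * tol)
    }
    vn <- vertex_normals(wrap)
    wrap$vertices <- wrap$vertices + vn * push
  }
  list(mesh = wrap)
}

#' Select the smallest tightly-wrapping alpha
#'
#' Sweeps alpha over a geometric grid from the vertex density to the
#' bounding-box diagonal and returns (to 5% relative tolerance, via a final
#' bisection) the smallest alpha whose wrap has reached the exposed-area
#' plateau: increasing alpha further changes the wrap area by less than
#' `plateau_tol`. Below this value the wrap still descends into sulci; above
#' it all sulci are bridged and the wrap only rounds off slowly, so the
#' plateau onset is the "minimum alpha that tightly wraps the surface".
#'
#' @param pial a closed [triangle_mesh()].
#' @param rel_tol relative tolerance on the returned alpha.
#' @param plateau_tol relative area change regarded as stable; the default 2%
#'   sits above the area jitter of the coarse selection grid while bridging
#'   transitions change the area by far more.
#' @param step geometric sweep factor.
#' @return alpha in mm.
#' @export
select_alpha <- function(pial, rel_tol = 0.05, plateau_tol = 0.02, step = 1.3) {
  dens <- vertex_density(pial)
  bb <- apply(pial$vertices, 2L, range)
  diag <- sqrt(sum((bb[2L, ] - bb[1L, ])^2))
  lo <- dens
  hi <- diag / 3
  if (hi <= lo) return(lo)
  alphas <- lo * step^(0:ceiling(log(hi / lo) / log(step)))
  alphas <- alphas[alphas <= hi]
  if (length(alphas) < 2L) return(lo)
  # one fixed coarse grid for the whole sweep keeps the area estimates
  # comparable across alphas (resolution-induced jitter cancels)
  h_sel <- max(dens, hi / 12)
  areas <- vapply(alphas, function(a)
    surface_area(wrap_mesh_at(pial, a, voxel = h_sel, smooth_iters = 10L)$mesh),
    numeric(1))
  n <- length(areas)
  stable <- abs(diff(areas)) / areas[-n] < plateau_tol
  k <- n
  for (i in rev(seq_len(n - 1L))) {
    if (stable[i]) k <- i else break
  }
  if (k == 1L) return(alphas[1L])
  # refine between alphas[k-1] (not yet stable) and alphas[k]
  a_lo <- alphas[k - 1L]; a_hi <- alphas[k]
  a_ref <- areas[k]
  while (a_hi / a_lo > 1 + rel_tol) {
    mid <- sqrt(a_lo * a_hi)
    am <- surface_area(wrap_mesh_at(pial, mid, voxel = h_sel, smooth_iters = 10L)$mesh)
    if (abs(am - a_ref) / a_ref < plateau_tol) a_hi <- mid else a_lo <- mid
  }
  a_hi
}

#' Per-vertex sulcal depth
#'
#' Closest distance from each pial vertex to the alpha-surface triangles,
#' then smoothed with two iterations of one-ring weighted averaging like all
#' local surface measures.
#'
#' @param pial the pial [triangle_mesh()].
#' @param wrap an `alpha_surface` (or a [triangle_mesh()] wrap).
#' @param smooth_iters measure-smoothing iterations (default 2).
#' @return depth [vertex_field()] on the pial mesh (mm, >= 0).
#' @export
sulcal_depth <- function(pial, wrap, smooth_iters = 2L) {
  wm <- if (inherits(wrap, "alpha_surface")) wrap$mesh else wrap
  d <- as.numeric(closest_distance(pial$vertices, wm))
  f <- smooth_vertex_field(pial, vertex_field(d, pial, units = "mm"),
                           iterations = smooth_iters)
  vertex_field(pmax(as.numeric(f), 0), pial, units = "mm")
}
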