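#' Mesh conditioning parameters
#'
#' Settings for the normalization/denoising stage applied to each surface
#' before any measure is computed. `target_density` is the desired sampling
#' spacing in mm (square root of area per vertex); `NULL` leaves the sampling
#' untouched. Taubin smoothing first shrinks with factor `taubin_shrink`
#' (lambda) and then inflates back with `taubin_inflate` (mu, negative), whose
#' magnitude must exceed lambda so the surface is inflated back by more than
#' it was shrunk.
#'
#' @param target_density target vertex spacing in mm, or `NULL`.
#' @param laplacian_iters,laplacian_factor Laplacian smoothing iterations and
#'   step fraction in (0, 1].
#' @param taubin_iters,taubin_shrink,taubin_inflate Taubin smoothing
#'   iterations, lambda in (0, 1) and mu < 0 with |mu| > lambda.
#' @param field_smooth_iters iterations of weighted averaging applied to every
#'   local surface measure (default 2).
#' @param field_smooth_weights `"uniform"` or `"invdist"` one-ring weights.
#' @return a `conditioning_config` list.
#' @export
conditioning_config <- function(target_density = NULL,
                                laplacian_iters = 5L, laplacian_factor = 0.5,
                                taubin_iters = 10L, taubin_shrink = 0.5,
                                taubin_inflate = -0.53,
                                field_smooth_iters = 2L,
                                field_smooth_weights = c("uniform", "invdist")) {
  field_smooth_weights <- match.arg(field_smooth_weights)
  if (!is.null(target_density) && target_density <= 0)
    stop("target_density must be > 0")
  if (laplacian_factor <= 0 || laplacian_factor > 1)
    stop("laplacian_factor must be in (0, 1]")
  if (taubin_shrink <= 0 || taubin_shrink >= 1) stop("taubin_shrink must be in (0, 1)")
  if (taubin_inflate >= 0) stop("taubin_inflate must be negative")
  if (abs(taubin_inflate) <= taubin_shrink)
    stop("|taubin_inflate| must exceed taubin_shrink (inflate-back magnitude ",
         "must exceed the shrink magnitude)")
  structure(list(target_density = target_density,
                 laplacian_iters = as.integer(laplacian_iters),
                 laplacian_factor = laplacian_factor,
                 taubin_iters = as.integer(taubin_iters),
                 taubin_shrink = taubin_shrink,
                 taubin_inflate = taubin_inflate,
                 field_smooth_iters = as.integer(field_smooth_iters),
                 field_smooth_weights = field_smooth_weights),
            class = "conditioning_config")
}

#' Vertex density of a mesh
#'
#' Square root of total surface area divided by the number of vertices: the
#' mean sampling spacing of the mesh in mm.
#'
#' @param mesh a [triangle_mesh()].
#' @return spacing in mm.
#' @export
vertex_density <- function(mesh) {
  if (n_faces(mesh) == 0L) stop("vertex_density() needs a mesh with faces")
  a <- surface_area(mesh)
  if (a <= 0) stop("degenerate geometry: mesh '", mesh$name, "' has zero area")
  sqrt(a / n_vertices(mesh))
}

#' Resample a mesh to a target triangle count
#'
#' Midpoint subdivision (by factors of 4) and/or shortest-edge decimation
#' until the face count is within 5% of `target_triangles`. Topology
#' (closedness, genus) is preserved; decimation collapses only edges that
#' satisfy the manifold link condition and do not flip face normals.
#'
#' @param mesh a closed [triangle_mesh()].
#' @param target_triangles desired face count (>= 20).
#' @return remeshed [triangle_mesh()].
#' @export
remesh_to_target <- function(mesh, target_triangles) {
  if (target_triangles < 20L) stop("target_triangles must be >= 20")
  if (!is_closed_mesh(mesh))
    stop("remesh_to_target() requires a closed mesh; '", mesh$name, "' is open")
  chi0 <- euler_characteristic(mesh)
  while (n_faces(mesh) < target_triangles / 1.05)
    mesh <- subdivide_midpoint(mesh)
  if (n_faces(mesh) > target_triangles * 1.05)
    mesh <- decimate_mesh(mesh, target_triangles)
  chi1 <- euler_characteristic(mesh)
  if (!is_closed_mesh(mesh) || chi1 != chi0)
    stop("remeshing broke the topology: Euler characteristic ", chi0, " -> ", chi1)
  mesh
}

# row-normalized one-ring averaging operator (self excluded)
uniform_ring_operator <- function(mesh) {
  A <- vertex_adjacency(mesh)
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  Matrix::Diagonal(x = 1 / deg) %*% A
}

#' Laplacian mesh smoothing
#'
#' Each iteration moves every vertex by `factor` times the offset from the
#' vertex to the uniform centroid of its one-ring. Shrinks closed surfaces;
#' use [taubin_smooth()] when the geometry must be preserved.
#'
#' @param mesh a [triangle_mesh()].
#' @param iterations number of passes (>= 0).
#' @param factor step fraction in (0, 1].
#' @return smoothed mesh (connectivity unchanged).
#' @export
laplacian_smooth <- function(mesh, iterations = 5L, factor = 0.5) {
  if (iterations < 0) stop("iterations must be >= 0")
  if (factor <= 0 || factor > 1) stop("factor must be in (0, 1]")
  if (iterations == 0L) return(mesh)
  W <- uniform_ring_operator(mesh)
  V <- mesh$vertices
  for (i in seq_len(iterations))
    V <- V + factor * (as.matrix(W %*% V) - V)
  mesh$vertices <- V
  mesh
}

#' Taubin (lambda/mu) mesh smoothing
#'
#' Alternates a shrink step (`shrink` = lambda > 0) and an inflate-back step
#' (`inflate` = mu < 0, with |mu| > lambda) of the same one-ring update, which
#' denoises while approximately preserving the global shape and volume.
#'
#' @param mesh a [triangle_mesh()].
#' @param iterations number of lambda+mu passes (>= 0).
#' @param shrink lambda in (0, 1).
#' @param inflate mu < 0, |mu| > lambda.
#' @return smoothed mesh (connectivity unchanged).
#' @export
taubin_smooth <- function(mesh, iterations = 10L, shrink = 0.5, inflate = -0.53) {
  if (iterations < 0) stop("iterations must be >= 0")
  if (shrink <= 0 || shrink >= 1) stop("shrink (lambda) must be in (0, 1)")
  if (inflate >= 0 || abs(inflate) <= shrink)
    stop("inflate (mu) must be negative with |mu| > lambda")
  if (iterations == 0L) return(mesh)
  W <- uniform_ring_operator(mesh)
  V <- mesh$vertices
  for (i in seq_len(iterations)) {
    V <- V + shrink * (as.matrix(W %*% V) - V)
    V <- V + inflate * (as.matrix(W %*% V) - V)
  }
  mesh$vertices <- V
  mesh
}

#' Smooth a per-vertex measure over the surface
#'
#' Each iteration replaces the value at a vertex by the weighted mean over the
#' vertex and its one-ring (uniform weights by default, inverse edge length
#' optionally). Vertices excluded by `exclude_zero` (e.g. floored thickness
#' zeros masking the medial wall) keep their value and are left out of every
#' neighbourhood average.
#'
#' @param mesh the owning [triangle_mesh()].
#' @param field a [vertex_field()] or numeric vector aligned to `mesh`.
#' @param iterations smoothing passes (default 2).
#' @param weights `"uniform"` or `"invdist"`.
#' @param exclude_zero treat exact zeros as masked.
#' @return smoothed [vertex_field()].
#' @export
smooth_vertex_field <- function(mesh, field, iterations = 2L,
                                weights = c("uniform", "invdist"),
                                exclude_zero = FALSE) {
  weights <- match.arg(weights)
  check_alignment(field, mesh)
  units <- attr(field, "units") %||% ""
  x <- as.numeric(field)
  if (iterations == 0L) return(vertex_field(x, mesh, units = units))
  e <- mesh_edges(mesh)
  nv <- n_vertices(mesh)
  w <- if (weights == "uniform") rep(1, nrow(e)) else {
    len <- sqrt(rowSums((mesh$vertices[e[, 1L], , drop = FALSE] -
                         mesh$vertices[e[, 2L], , drop = FALSE])^2))
    1 / pmax(len, 1e-12)
  }
  A <- Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L], seq_len(nv)),
                            j = c(e[, 2L], e[, 1L], seq_len(nv)),
                            x = c(w, w, rep(1, nv)), dims = c(nv, nv))
  if (exclude_zero) {
    keep <- x != 0
    for (i in seq_len(iterations)) {
      m <- as.numeric(A %*% (x * keep))
      s <- as.numeric(A %*% as.numeric(keep))
      xn <- ifelse(keep & s > 0, m / pmax(s, 1e-12), x)
      x <- xn
    }
  } else {
    s <- as.numeric(A %*% rep(1, nv))
    for (i in seq_len(iterations))
      x <- as.numeric(A %*% x) / s
  }
  vertex_field(x, mesh, units = units)
}
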