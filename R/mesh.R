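#' Triangulated surface mesh
#'
#' The carrier of all geometry in the package: an oriented triangle mesh with
#' vertex coordinates in millimetres. Faces index vertices 1-based (the R
#' convention); file formats that store 0-based indices are converted at the
#' I/O boundary.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param name label for the surface, e.g. `"lh.pial"`.
#' @param validate check the mesh invariants (finite coordinates, in-range
#'   indices, no degenerate faces).
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `name`.
#' @export
triangle_mesh <- function(vertices, faces, name = "mesh", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns (x, y, z in mm)")
  if (nrow(faces) > 0L && ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) == 0L) faces <- matrix(integer(0), 0L, 3L)
  mesh <- structure(list(vertices = vertices, faces = faces, name = name),
                    class = "triangle_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (!all(is.finite(v))) stop("mesh '", mesh$name, "' has non-finite vertex coordinates")
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > nrow(v))
      stop("mesh '", mesh$name, "' has face indices outside 1..", nrow(v))
    dg <- f[, 1L] == f[, 2L] | f[, 1L] == f[, 3L] | f[, 2L] == f[, 3L]
    if (any(dg))
      stop("mesh '", mesh$name, "' has ", sum(dg), " degenerate face(s) (repeated vertex)")
  }
  invisible(mesh)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh '", x$name, "': ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces\n", sep = "")
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

#' Per-vertex scalar field aligned to a mesh
#'
#' @param values numeric vector, one value per vertex of the owning mesh.
#' @param mesh the owning [triangle_mesh()] (or its vertex count).
#' @param units unit label: `"mm"`, `"mm^-1"`, `"mm^-2"` or `""`.
#' @param mesh_name label of the owning mesh.
#' @return object of class `vertex_field`: numeric vector with attributes
#'   `mesh_name` and `units`.
#' @export
vertex_field <- function(values, mesh, units = "", mesh_name = NULL) {
  nv <- if (inherits(mesh, "triangle_mesh")) n_vertices(mesh) else as.integer(mesh)
  if (is.null(mesh_name) && inherits(mesh, "triangle_mesh")) mesh_name <- mesh$name
  values <- as.numeric(values)
  if (length(values) != nv)
    stop("vertex field length (", length(values), ") does not match mesh vertex count (",
         nv, ")")
  structure(values, mesh_name = mesh_name %||% "mesh", units = units,
            class = "vertex_field")
}

#' @export
print.vertex_field <- function(x, ...) {
  cat("vertex_field on '", attr(x, "mesh_name"), "' (", length(x), " vertices",
      if (nzchar(attr(x, "units"))) paste0(", ", attr(x, "units")), ")\n", sep = "")
  print(summary(unclass(x)))
  invisible(x)
}

field_values <- function(x) as.numeric(unclass(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

check_alignment <- function(field, mesh) {
  if (length(field) != n_vertices(mesh))
    stop("field has ", length(field), " values but mesh '", mesh$name, "' has ",
         n_vertices(mesh), " vertices")
  invisible(TRUE)
}

# ---- connectivity ----------------------------------------------------------

# directed edges as a 3F x 2 matrix
directed_edges <- function(mesh) {
  f <- mesh$faces
  cbind(c(f[, 1L], f[, 2L], f[, 3L]), c(f[, 2L], f[, 3L], f[, 1L]))
}

#' Undirected edge list of a mesh
#' @param mesh a [triangle_mesh()].
#' @return integer matrix with one unique undirected edge per row.
#' @export
mesh_edges <- function(mesh) {
  de <- directed_edges(mesh)
  nv <- n_vertices(mesh)
  key <- pmin(de[, 1L], de[, 2L]) * (nv + 1) + pmax(de[, 1L], de[, 2L])
  e <- de[!duplicated(key), , drop = FALSE]
  cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
}

#' Euler characteristic V - E + F
#' @param mesh a [triangle_mesh()].
#' @return integer; 2 for a closed genus-0 surface.
#' @export
euler_characteristic <- function(mesh) {
  n_vertices(mesh) - nrow(mesh_edges(mesh)) + n_faces(mesh)
}

# multiplicities of undirected edges (sorted numeric keys)
edge_multiplicities <- function(mesh) {
  de <- directed_edges(mesh)
  nv <- n_vertices(mesh)
  key <- sort(pmin(de[, 1L], de[, 2L]) * (nv + 1) + pmax(de[, 1L], de[, 2L]))
  r <- rle(key)
  list(key = r$values, count = r$lengths)
}

#' Is the mesh closed (watertight)?
#'
#' Every undirected edge must be shared by exactly two faces.
#' @param mesh a [triangle_mesh()].
#' @return logical.
#' @export
is_closed_mesh <- function(mesh) {
  if (n_faces(mesh) == 0L) return(FALSE)
  all(edge_multiplicities(mesh)$count == 2L)
}

#' Is the mesh consistently oriented?
#'
#' For a consistently oriented mesh every interior edge is traversed once in
#' each direction, i.e. no directed edge repeats.
#' @param mesh a [triangle_mesh()].
#' @return logical.
#' @export
is_oriented_mesh <- function(mesh) {
  de <- directed_edges(mesh)
  nv <- n_vertices(mesh)
  !anyDuplicated(de[, 1L] * (nv + 1) + de[, 2L])
}

# edges bounding only one face (empty for closed meshes)
boundary_vertices <- function(mesh) {
  em <- edge_multiplicities(mesh)
  nv <- n_vertices(mesh)
  open_keys <- em$key[em$count == 1L]
  if (length(open_keys) == 0L) return(integer(0))
  sort(unique(c(open_keys %/% (nv + 1), open_keys %% (nv + 1))))
}

# connected components of the vertex graph (union-find); returns labels
vertex_components <- function(mesh) {
  cpp_components(mesh_edges(mesh), n_vertices(mesh))
}

# sparse vertex adjacency (pattern, no self loops)
vertex_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  nv <- n_vertices(mesh)
  Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
                       x = 1, dims = c(nv, nv))
}

# list of one-ring neighbours per vertex
one_ring <- function(mesh) {
  e <- mesh_edges(mesh)
  split(c(e[, 2L], e[, 1L]), c(e[, 1L], e[, 2L]))
}

# ---- geometry --------------------------------------------------------------

face_cross <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  u <- v[f[, 2L], , drop = FALSE] - a
  w <- v[f[, 3L], , drop = FALSE] - a
  cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
        u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
        u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
}

face_areas <- function(mesh) {
  cr <- face_cross(mesh)
  0.5 * sqrt(rowSums(cr^2))
}

face_normals <- function(mesh) {
  cr <- face_cross(mesh)
  nrm <- sqrt(rowSums(cr^2))
  nrm[nrm == 0] <- 1
  cr / nrm
}

#' Total surface area
#'
#' Sum of all triangle areas of the mesh, in mm^2.
#' @param mesh a [triangle_mesh()].
#' @return area in mm^2.
#' @export
surface_area <- function(mesh) sum(face_areas(mesh))

#' Enclosed volume of a closed mesh
#'
#' Signed-tetrahedron sum from the origin; the result is reported positive
#' regardless of the stored orientation. Open meshes are rejected.
#' @param mesh a closed [triangle_mesh()].
#' @return volume in mm^3.
#' @export
enclosed_volume <- function(mesh) {
  if (!is_closed_mesh(mesh))
    stop("enclosed_volume() requires a closed mesh; '", mesh$name, "' has boundary edges")
  abs(signed_volume(mesh))
}

signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c3 <- v[f[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * c3[, 3L] - b[, 3L] * c3[, 2L]) -
      a[, 2L] * (b[, 1L] * c3[, 3L] - b[, 3L] * c3[, 1L]) +
      a[, 3L] * (b[, 1L] * c3[, 2L] - b[, 2L] * c3[, 1L])) / 6
}

# flip the orientation of every face
flip_orientation <- function(mesh) {
  mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}

# outward-orient a closed mesh (positive signed volume)
orient_outward <- function(mesh) {
  if (is_closed_mesh(mesh) && signed_volume(mesh) < 0) flip_orientation(mesh) else mesh
}

#' Per-vertex unit normals
#'
#' Area-weighted average of incident face normals. For closed meshes the
#' orientation is checked via the signed volume and flipped to outward if
#' necessary.
#' @param mesh an oriented [triangle_mesh()].
#' @return numeric matrix of unit normals, one row per vertex.
#' @export
vertex_normals <- function(mesh) {
  mesh <- orient_outward(mesh)
  cr <- face_cross(mesh)          # length = 2 * area, along face normal
  nv <- n_vertices(mesh)
  f <- mesh$faces
  nx <- rowsum(c(cr[, 1L], cr[, 1L], cr[, 1L]), c(f), reorder = TRUE)
  ny <- rowsum(c(cr[, 2L], cr[, 2L], cr[, 2L]), c(f), reorder = TRUE)
  nz <- rowsum(c(cr[, 3L], cr[, 3L], cr[, 3L]), c(f), reorder = TRUE)
  out <- matrix(0, nv, 3L)
  idx <- as.integer(rownames(nx))
  out[idx, 1L] <- nx; out[idx, 2L] <- ny; out[idx, 3L] <- nz
  nrm <- sqrt(rowSums(out^2))
  bad <- which(nrm == 0 & tabulate(f, nv) > 0L)
  if (length(bad))
    stop("degenerate vertex star: zero-norm normal at vertex ", bad[1L])
  nrm[nrm == 0] <- 1
  out / nrm
}

#' Uniformly scale a mesh about the origin
#' @param mesh a [triangle_mesh()].
#' @param s positive scale factor.
#' @export
scale_mesh <- function(mesh, s) {
  stopifnot(s > 0)
  mesh$vertices <- mesh$vertices * s
  mesh
}

#' Translate a mesh
#' @param mesh a [triangle_mesh()].
#' @param offset length-3 numeric offset in mm.
#' @export
translate_mesh <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2L, offset, "+")
  mesh
}

# concatenate two meshes into one (disjoint union), e.g. both hemispheres
combine_meshes <- function(a, b, name = paste(a$name, b$name, sep = "+")) {
  triangle_mesh(rbind(a$vertices, b$vertices),
                rbind(a$faces, b$faces + n_vertices(a)),
                name = name)
}

# ---- primitive meshes ------------------------------------------------------

icosahedron <- function(R = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2)) * R
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  orient_outward(triangle_mesh(v, f, name = "icosahedron"))
}

#' Midpoint subdivision of a mesh
#'
#' Splits every triangle into four by inserting edge midpoints; the new
#' vertices lie on the original surface (no smoothing).
#' @param mesh a [triangle_mesh()].
#' @return subdivided mesh with 4x the face count.
#' @export
subdivide_midpoint <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e <- mesh_edges(mesh)
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  mid_idx <- setNames(nrow(v) + seq_len(nrow(e)), key(e[, 1L], e[, 2L]))
  mids <- (v[e[, 1L], , drop = FALSE] + v[e[, 2L], , drop = FALSE]) / 2
  m12 <- mid_idx[key(f[, 1L], f[, 2L])]
  m23 <- mid_idx[key(f[, 2L], f[, 3L])]
  m31 <- mid_idx[key(f[, 3L], f[, 1L])]
  newf <- rbind(cbind(f[, 1L], m12, m31),
                cbind(f[, 2L], m23, m12),
                cbind(f[, 3L], m31, m23),
                cbind(m12, m23, m31))
  triangle_mesh(rbind(v, mids), unname(newf), name = mesh$name)
}

#' Icosphere (subdivided icosahedron)
#'
#' @param R radius in mm.
#' @param subdivisions number of midpoint-subdivision passes; vertex counts
#'   are 12, 42, 162, 642, 2562, ... and face counts 20 * 4^n.
#' @return a closed [triangle_mesh()].
#' @export
icosphere <- function(R = 1, subdivisions = 3L) {
  m <- icosahedron(1)
  for (i in seq_len(subdivisions)) {
    m <- subdivide_midpoint(m)
    m$vertices <- m$vertices / sqrt(rowSums(m$vertices^2))
  }
  m$vertices <- m$vertices * R
  m$name <- sprintf("icosphere_R%g_s%d", R, subdivisions)
  m
}

#' Triangulated torus
#'
#' Ring radius `R`, tube radius `r`, sampled on an `nu` x `nv` grid.
#' @param R ring (major) radius in mm.
#' @param r tube (minor) radius in mm.
#' @param nu,nv samples around the ring and the tube.
#' @return a closed [triangle_mesh()].
#' @export
torus_mesh <- function(R = 10, r = 3, nu = 96L, nv = 48L) {
  iu <- rep(seq_len(nu) - 1L, times = nv)
  iv <- rep(seq_len(nv) - 1L, each = nu)
  u <- 2 * pi * iu / nu
  vth <- 2 * pi * iv / nv
  vx <- (R + r * cos(vth)) * cos(u)
  vy <- (R + r * cos(vth)) * sin(u)
  vz <- r * sin(vth)
  id <- function(i, j) (i %% nu) + nu * (j %% nv) + 1L
  i <- rep(seq_len(nu) - 1L, times = nv)
  j <- rep(seq_len(nv) - 1L, each = nu)
  f1 <- cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L))
  f2 <- cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
  orient_outward(triangle_mesh(cbind(vx, vy, vz), rbind(f1, f2),
                               name = sprintf("torus_R%g_r%g", R, r)))
}

#' Triangulated axis-aligned box surface
#' @param side edge length (or length-3 vector) in mm.
#' @param center box center.
#' @return a closed [triangle_mesh()] with 12 faces.
#' @export
box_mesh <- function(side = 1, center = c(0, 0, 0)) {
  s <- rep(side, length.out = 3L) / 2
  g <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  v <- sweep(sweep(g, 2L, s, "*"), 2L, center, "+")
  # corner order from expand.grid: x fastest, then y, then z
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = -s
    c(5, 6, 8), c(5, 8, 7),   # z = +s
    c(1, 5, 7), c(1, 7, 3),   # x = -s
    c(2, 4, 8), c(2, 8, 6),   # x = +s
    c(1, 2, 6), c(1, 6, 5),   # y = -s
    c(3, 7, 8), c(3, 8, 4))   # y = +s
  triangle_mesh(v, f, name = "box")
}

#' Triangulated ellipsoid (anisotropically scaled icosphere)
#' @param a,b,c semi-axes in mm.
#' @param subdivisions icosphere subdivision level.
#' @return a closed [triangle_mesh()].
#' @export
ellipsoid_mesh <- function(a = 10, b = 7, c = 5, subdivisions = 4L) {
  m <- icosphere(1, subdivisions)
  m$vertices <- sweep(m$vertices, 2L, c(a, b, c), "*")
  m$name <- sprintf("ellipsoid_%g_%g_%g", a, b, c)
  m
}
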