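#' Exact closest distances from points to a triangle mesh
#'
#' Minimum Euclidean distance from each query point to the target's triangle
#' set (point-to-triangle, not point-to-vertex), computed through a uniform
#' spatial grid over the triangles.
#'
#' @param points numeric matrix of query points (n x 3, mm).
#' @param target a [triangle_mesh()] with at least one face.
#' @return numeric vector of distances (mm) with attributes `foot` (closest
#'   points, n x 3) and `triangle` (1-based index of the closest face).
#' @export
closest_distance <- function(points, target) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  points <- as.matrix(points)
  if (n_faces(target) < 1L) stop("target mesh has no faces")
  res <- cpp_closest_on_mesh(points, target$vertices, target$faces - 1L)
  structure(res$dist, foot = res$foot, triangle = res$tri + 1L)
}

#' Thickness computation parameters
#'
#' @param floor thickness floor in mm; values below it (e.g. along the masked
#'   medial wall) are set to exactly zero. Default 0.5 mm.
#' @param exclude_zeros exclude exact zeros from all downstream thickness
#'   statistics (default on).
#' @return a `thickness_config` list.
#' @export
thickness_config <- function(floor = 0.5, exclude_zeros = TRUE) {
  if (floor < 0) stop("floor must be >= 0")
  structure(list(floor = floor, exclude_zeros = exclude_zeros),
            class = "thickness_config")
}

#' Bidirectional closest-point cortical thickness
#'
#' For each pial vertex: `d1` is the distance to the closest point on the
#' white surface, and `d2` the distance from that foot point back to the
#' closest point on the pial surface; thickness is `(d1 + d2) / 2`, reported
#' at the pial vertex. Values below `cfg$floor` are set to exactly zero.
#'
#' @param pial,white closed [triangle_mesh()]es of the same cortex with
#'   comparable vertex counts.
#' @param cfg a [thickness_config()].
#' @return thickness [vertex_field()] on the pial mesh (mm).
#' @export
cortical_thickness <- function(pial, white, cfg = thickness_config()) {
  d1 <- closest_distance(pial$vertices, white)
  foot <- attr(d1, "foot")
  d2 <- closest_distance(foot, pial)
  th <- (as.numeric(d1) + as.numeric(d2)) / 2
  # interpenetration check: white vertices outside the pial surface
  dw <- closest_distance(white$vertices, pial)
  fn <- face_normals(orient_outward(pial))
  tri <- attr(dw, "triangle")
  side <- rowSums((white$vertices - attr(dw, "foot")) * fn[tri, , drop = FALSE])
  n_out <- sum(side > 1e-6 & as.numeric(dw) > 1e-6)
  if (n_out > 0.01 * n_vertices(white))
    warning("white surface lies outside the pial surface at ", n_out,
            " of ", n_vertices(white), " vertices")
  th[th < cfg$floor] <- 0
  vertex_field(th, pial, units = "mm")
}
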