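#' Per-vertex principal curvatures by local quadric fitting
#'
#' At each vertex the two-ring neighbourhood is projected into the tangent
#' frame of the vertex normal and a quadric
#' `w = p u + q v + a u^2 + b u v + c v^2` is fitted by least squares; the
#' principal curvatures are the eigenvalues of the Weingarten map built from
#' the first and second fundamental forms of the fit. The window grows to
#' three rings when the fit is rank-deficient. Sign convention: a closed
#' convex surface with outward normals has positive curvatures.
#'
#' On open meshes, boundary vertices are flagged invalid (`valid = FALSE`)
#' and should be excluded from statistics.
#'
#' @param mesh a conditioned [triangle_mesh()].
#' @return object of class `curvature_bundle`: list with per-vertex `k1`
#'   (larger), `k2`, `K` (Gaussian, mm^-2), `H` (mean, mm^-1), `flat` and
#'   `valid` flags.
#' @export
principal_curvatures <- function(mesh) {
  nv <- n_vertices(mesh)
  nrm <- vertex_normals(mesh)
  A1 <- vertex_adjacency(mesh)
  A2 <- A1 %*% A1
  ring1 <- sparse_neighbours(A1)
  ring2 <- sparse_neighbours(A2, union_with = ring1)
  V <- mesh$vertices
  bvs <- boundary_vertices(mesh)
  valid <- rep(TRUE, nv)
  valid[bvs] <- FALSE
  k1 <- k2 <- numeric(nv)
  ring3 <- NULL
  for (i in seq_len(nv)) {
    if (!valid[i]) { k1[i] <- NA_real_; k2[i] <- NA_real_; next }
    nb <- ring2[[i]]
    ks <- quadric_curvature(V, nrm[i, ], i, nb)
    if (is.null(ks)) {
      if (is.null(ring3)) ring3 <- sparse_neighbours(A2 %*% A1, union_with = ring2)
      ks <- quadric_curvature(V, nrm[i, ], i, ring3[[i]])
    }
    if (is.null(ks)) { valid[i] <- FALSE; k1[i] <- NA_real_; k2[i] <- NA_real_; next }
    k1[i] <- ks[1L]; k2[i] <- ks[2L]
  }
  flat <- !is.na(k1) & abs(k1) < 1e-8 & abs(k2) < 1e-8
  structure(list(k1 = k1, k2 = k2, K = k1 * k2, H = (k1 + k2) / 2,
                 flat = flat, valid = valid, mesh_name = mesh$name),
            class = "curvature_bundle")
}

# neighbour index lists from a sparse pattern matrix (self removed)
sparse_neighbours <- function(A, union_with = NULL) {
  At <- methods::as(methods::as(A, "generalMatrix"), "TsparseMatrix")
  nb <- split(At@j + 1L, factor(At@i + 1L, levels = seq_len(nrow(A))))
  nb <- lapply(seq_along(nb), function(i) setdiff(nb[[i]], i))
  if (!is.null(union_with))
    nb <- lapply(seq_along(nb), function(i) union(nb[[i]], union_with[[i]]))
  nb
}

quadric_curvature <- function(V, n, i, nb) {
  if (length(nb) < 6L) return(NULL)
  # tangent frame
  ax <- if (abs(n[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ax - sum(ax * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(n, e1)
  d <- sweep(V[nb, , drop = FALSE], 2L, V[i, ], "-")
  u <- d %*% e1; v <- d %*% e2; w <- d %*% n
  X <- cbind(u, v, u^2, u * v, v^2)
  qrX <- qr(X)
  if (qrX$rank < 5L) return(NULL)
  cf <- qr.coef(qrX, w)
  p <- cf[1L]; q <- cf[2L]; a <- cf[3L]; b <- cf[4L]; cc <- cf[5L]
  den <- sqrt(1 + p^2 + q^2)
  II <- matrix(c(2 * a, b, b, 2 * cc), 2L) / den
  I1 <- matrix(c(1 + p^2, p * q, p * q, 1 + q^2), 2L)
  W <- solve(I1, II)
  W <- (W + t(W)) / 2
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  # outward normal + convex surface curving below the tangent plane => flip
  ks <- -sort(ev)
  c(ks[1L], ks[2L])
}

#' Koenderink shape index from principal curvatures
#'
#' `s = (2/pi) atan((k1 + k2) / (k1 - k2))` with `k1 >= k2`; umbilic points
#' (`k1 = k2 != 0`) map to +/-1 and flat points to 0 (carrying a flat flag).
#' `orientation = "koenderink"` returns the raw index (cap = +1);
#' `orientation = "paper"` negates it so that convex shapes occupy
#' (-1, -0.375), the convention used for all classification in this package.
#'
#' @param bundle a `curvature_bundle` from [principal_curvatures()], or a
#'   list with `k1`, `k2`.
#' @param orientation `"paper"` (convex negative, default) or `"koenderink"`.
#' @return a [vertex_field()] (dimensionless) with attribute `flat`.
#' @export
shape_index <- function(bundle, orientation = c("paper", "koenderink")) {
  orientation <- match.arg(orientation)
  k1 <- bundle$k1; k2 <- bundle$k2
  stopifnot(all(k1 >= k2 - 1e-12, na.rm = TRUE))
  scale <- pmax(abs(k1), abs(k2), 1e-30)
  umb <- !is.na(k1) & abs(k1 - k2) <= 1e-12 * pmax(scale, 1)
  flat <- umb & abs(k1) < 1e-8
  s <- (2 / pi) * atan((k1 + k2) / (k1 - k2))
  s[umb] <- sign(k1[umb])
  s[flat] <- 0
  if (orientation == "paper") s <- -s
  structure(vertex_field(ifelse(is.na(s), 0, s), length(k1),
                         units = "", mesh_name = bundle$mesh_name %||% "mesh"),
            flat = flat, orientation = orientation)
}

SHAPE_MINOR_LEVELS <- c("cup", "trough", "rut", "saddle rut", "saddle",
                        "saddle ridge", "ridge", "dome", "cap")
SHAPE_MAJOR_LEVELS <- c("concave", "saddle", "convex")

#' Classify vertices into 9 minor and 3 major shape categories
#'
#' Bands of width 1/4 with edges at +/-1/8, +/-3/8, +/-5/8, +/-7/8 of the
#' shape index (in the "paper" orientation: cap at -1 through cup at +1).
#' Band edges belong to the band closer to zero, so the three-way boundary at
#' +/-0.375 ties toward saddle. The major label is determined by the minor
#' one: cap/dome/ridge are convex, saddle ridge/saddle/saddle rut are saddle,
#' rut/trough/cup are concave. Flat-flagged vertices classify as saddle.
#'
#' @param si shape-index [vertex_field()] in the paper orientation
#'   (convex negative), as returned by [shape_index()] by default.
#' @return object of class `shape_labels`: list with factors `minor` (codes
#'   0-8 = cup..cap) and `major` (codes 0/1/2 = concave/saddle/convex).
#' @export
classify_shapes <- function(si) {
  s <- as.numeric(si)
  if (any(s < -1 - 1e-9 | s > 1 + 1e-9))
    stop("shape index out of range [-1, 1]: ",
         paste(head(round(s[s < -1 | s > 1], 4)), collapse = ", "))
  s <- pmin(1, pmax(-1, s))
  if (!is.null(attr(si, "orientation")) && attr(si, "orientation") == "koenderink")
    s <- -s
  breaks <- c(-8, -7, -5, -3, -1, 1, 3, 5, 7) / 8
  # paper orientation: band 1 = cap (si near -1) ... band 9 = cup (si near +1)
  band <- integer(length(s))
  neg <- s < 1 / 8
  # negative side: left-closed bands [edge_outer, edge_inner) put edges in the
  # inner (closer to zero) band
  band[neg] <- findInterval(s[neg], breaks)
  pos <- !neg
  band[pos] <- 10L - findInterval(-s[pos], breaks)
  band[band < 1L] <- 1L
  band[band > 9L] <- 9L
  flat <- attr(si, "flat")
  if (!is.null(flat)) band[flat] <- 5L
  # band 1..9 along paper si = cap..cup; map to canonical cup..cap codes
  minor <- factor(SHAPE_MINOR_LEVELS[10L - band], levels = SHAPE_MINOR_LEVELS)
  major_of_minor <- c(rep("concave", 3L), rep("saddle", 3L), rep("convex", 3L))
  major <- factor(major_of_minor[as.integer(minor)], levels = SHAPE_MAJOR_LEVELS)
  structure(list(minor = minor, major = major), class = "shape_labels")
}

#' Integer codes of shape labels
#'
#' Minor codes 0-8 are cup, trough, rut, saddle rut, saddle, saddle ridge,
#' ridge, dome, cap; major codes 0/1/2 are concave/saddle/convex.
#' @param labels a `shape_labels` object.
#' @return list with integer vectors `minor`, `major`.
#' @export
shape_codes <- function(labels) {
  list(minor = as.integer(labels$minor) - 1L,
       major = as.integer(labels$major) - 1L)
}
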