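#' Decimate a closed mesh by shortest-edge collapse
#'
#' Iteratively collapses the shortest edges to their midpoints, skipping any
#' collapse that violates the manifold link condition (the endpoints must
#' share exactly the two opposite vertices of the two incident faces) or that
#' flips the normal of a surviving face. Each collapse removes two faces, so
#' the target is reached near-exactly on a closed manifold.
#'
#' @param mesh a closed [triangle_mesh()].
#' @param target_faces desired face count.
#' @return decimated [triangle_mesh()].
#' @export
decimate_mesh <- function(mesh, target_faces) {
  if (!is_closed_mesh(mesh)) stop("decimate_mesh() requires a closed mesh")
  chi0 <- euler_characteristic(mesh)
  V <- mesh$vertices
  F <- mesh$faces
  guard <- 0L
  while (nrow(F) > target_faces && guard < 200L) {
    guard <- guard + 1L
    nv <- nrow(V)
    e <- cbind(pmin(c(F[, 1L], F[, 2L], F[, 3L]), c(F[, 2L], F[, 3L], F[, 1L])),
               pmax(c(F[, 1L], F[, 2L], F[, 3L]), c(F[, 2L], F[, 3L], F[, 1L])))
    e <- e[!duplicated(paste(e[, 1L], e[, 2L])), , drop = FALSE]
    len <- sqrt(rowSums((V[e[, 1L], , drop = FALSE] - V[e[, 2L], , drop = FALSE])^2))
    ord <- order(len)
    nbr <- lapply(split(c(e[, 2L], e[, 1L]), c(e[, 1L], e[, 2L])), unique)
    nbr_of <- function(i) {
      k <- as.character(i)
      if (k %in% names(nbr)) nbr[[k]] else integer(0)
    }
    finc <- split(rep(seq_len(nrow(F)), 3L), c(F))
    finc_of <- function(i) {
      k <- as.character(i)
      if (k %in% names(finc)) finc[[k]] else integer(0)
    }
    touched <- logical(nv)
    vmap <- seq_len(nv)
    removed_faces <- 0L
    collapses <- 0L
    budget <- (nrow(F) - target_faces) %/% 2L
    for (k in ord) {
      if (collapses >= budget && budget > 0L) break
      u <- e[k, 1L]; v <- e[k, 2L]
      if (touched[u] || touched[v]) next
      nu <- nbr_of(u); nvv <- nbr_of(v)
      common <- intersect(nu, nvv)
      if (length(common) != 2L) next
      mid <- (V[u, ] + V[v, ]) / 2
      # normal-flip check on surviving faces incident to u or v
      fids <- unique(c(finc_of(u), finc_of(v)))
      ok <- TRUE
      for (fi in fids) {
        tri <- F[fi, ]
        if (u %in% tri && v %in% tri) next  # face will be removed
        p <- V[tri, , drop = FALSE]
        n0 <- cross3(p[2L, ] - p[1L, ], p[3L, ] - p[1L, ])
        p2 <- p
        p2[tri == u | tri == v, ] <- rep(mid, each = sum(tri == u | tri == v))
        n1 <- cross3(p2[2L, ] - p2[1L, ], p2[3L, ] - p2[1L, ])
        if (sum(n0 * n1) <= 0) { ok <- FALSE; break }
      }
      if (!ok) next
      # volume-preserving placement: offset the midpoint along the local
      # normal so the signed volume of the incident face fan is unchanged
      # (plain midpoints shrink convex surfaces)
      vol_tri <- function(p1, p2, p3) {
        (p1[1L] * (p2[2L] * p3[3L] - p2[3L] * p3[2L]) -
         p1[2L] * (p2[1L] * p3[3L] - p2[3L] * p3[1L]) +
         p1[3L] * (p2[1L] * p3[2L] - p2[2L] * p3[1L])) / 6
    }
      vol_before <- 0; vol_after <- 0
      nsum <- c(0, 0, 0); asum <- 0
      for (fi in fids) {
        tri <- F[fi, ]
        p <- V[tri, , drop = FALSE]
        vol_before <- vol_before + vol_tri(p[1L, ], p[2L, ], p[3L, ])
        if (u %in% tri && v %in% tri) next
        p2 <- p
        p2[tri == u | tri == v, ] <- rep(mid, each = sum(tri == u | tri == v))
        vol_after <- vol_after + vol_tri(p2[1L, ], p2[2L, ], p2[3L, ])
        nf <- cross3(p2[2L, ] - p2[1L, ], p2[3L, ] - p2[1L, ])
        nsum <- nsum + nf
        asum <- asum + sqrt(sum(nf^2)) / 2
      }
      nlen <- sqrt(sum(nsum^2))
      if (nlen > 1e-12 && asum > 1e-12) {
        # fan volume is linear in a normal offset t: dV/dt = |sum of face
        # cross products| / 6; solve for the offset that cancels the loss
        t_off <- 6 * (vol_before - vol_after) / nlen
        if (abs(t_off) < len[k]) mid <- mid + nsum / nlen * t_off
      }
      V[u, ] <- mid
      vmap[v] <- u
      touched[c(u, v, nu, nvv)] <- TRUE
      removed_faces <- removed_faces + 2L
      collapses <- collapses + 1L
    }
    if (collapses == 0L) break
    F <- matrix(vmap[F], ncol = 3L)
    F <- F[!(F[, 1L] == F[, 2L] | F[, 2L] == F[, 3L] | F[, 1L] == F[, 3L]), , drop = FALSE]
  }
  # compact unused vertices
  used <- sort(unique(as.vector(F)))
  remap <- integer(nrow(V))
  remap[used] <- seq_along(used)
  out <- triangle_mesh(V[used, , drop = FALSE], matrix(remap[F], ncol = 3L),
                       name = mesh$name)
  chi1 <- euler_characteristic(out)
  if (!is_closed_mesh(out) || chi1 != chi0)
    stop("decimation broke the topology: Euler characteristic ", chi0, " -> ", chi1)
  out
}

cross3 <- function(u, w) {
  c(u[2L] * w[3L] - u[3L] * w[2L],
    u[3L] * w[1L] - u[1L] * w[3L],
    u[1L] * w[2L] - u[2L] * w[1L])
}
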