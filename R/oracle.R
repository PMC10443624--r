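#' Closed-form curvature oracle on analytic surfaces
#'
#' Exact Gaussian/mean/principal curvatures and shape index at points of a
#' sphere, ellipsoid, or torus, computed from the implicit-surface formulas
#' (gradient and Hessian of the defining function F = 0), entirely
#' independent of the discrete mesh estimator. Used to validate
#' [principal_curvatures()].
#'
#' @param kind `"sphere"`, `"ellipsoid"` or `"torus"`.
#' @param params named list: sphere `R`; ellipsoid `a`, `b`, `c`;
#'   torus `R` (ring), `r` (tube).
#' @param points numeric matrix of query points lying on the surface.
#' @param tol maximum allowed relative off-surface deviation of the points.
#' @param orientation shape-index orientation passed to the same formula as
#'   [shape_index()].
#' @return data.frame with columns `k1`, `k2`, `K`, `H`, `SI`.
#' @export
analytic_oracle <- function(kind = c("sphere", "ellipsoid", "torus"),
                            params, points, tol = 1e-6,
                            orientation = c("paper", "koenderink")) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  points <- as.matrix(points)
  x <- points[, 1L]; y <- points[, 2L]; z <- points[, 3L]
  n <- nrow(points)
  Fv <- switch(kind,
    sphere = (x^2 + y^2 + z^2) / params$R^2 - 1,
    ellipsoid = x^2 / params$a^2 + y^2 / params$b^2 + z^2 / params$c^2 - 1,
    torus = ((sqrt(x^2 + y^2) - params$R)^2 + z^2) / params$r^2 - 1)
  if (any(abs(Fv) > 100 * tol))
    stop("query point(s) off the ", kind, " surface beyond tolerance (max |F| = ",
         signif(max(abs(Fv)), 3), ")")
  grad <- matrix(0, n, 3L)
  hess <- array(0, c(n, 3L, 3L))
  if (kind == "sphere") {
    grad[] <- 2 * points
    for (k in 1:3) hess[, k, k] <- 2
  } else if (kind == "ellipsoid") {
    ax <- c(params$a, params$b, params$c)
    for (k in 1:3) {
      grad[, k] <- 2 * points[, k] / ax[k]^2
      hess[, k, k] <- 2 / ax[k]^2
    }
  } else {
    s <- sqrt(x^2 + y^2)
    R <- params$R
    grad[, 1L] <- 2 * x * (1 - R / s)
    grad[, 2L] <- 2 * y * (1 - R / s)
    grad[, 3L] <- 2 * z
    hess[, 1L, 1L] <- 2 * (1 - R / s) + 2 * R * x^2 / s^3
    hess[, 2L, 2L] <- 2 * (1 - R / s) + 2 * R * y^2 / s^3
    hess[, 1L, 2L] <- hess[, 2L, 1L] <- 2 * R * x * y / s^3
    hess[, 3L, 3L] <- 2
  }
  K <- H <- numeric(n)
  for (i in seq_len(n)) {
    g <- grad[i, ]
    Hm <- hess[i, , ]
    gn2 <- sum(g^2)
    adjH <- adjugate3(Hm)
    K[i] <- as.numeric(t(g) %*% adjH %*% g) / gn2^2
    H[i] <- (gn2 * sum(diag(Hm)) - as.numeric(t(g) %*% Hm %*% g)) / (2 * gn2^1.5)
  }
  disc <- pmax(H^2 - K, 0)
  k1 <- H + sqrt(disc)
  k2 <- H - sqrt(disc)
  si <- shape_index(list(k1 = k1, k2 = k2, mesh_name = "oracle"),
                    orientation = orientation)
  data.frame(k1 = k1, k2 = k2, K = K, H = H, SI = as.numeric(si))
}

adjugate3 <- function(M) {
  co <- matrix(0, 3L, 3L)
  for (i in 1:3) for (j in 1:3) {
    mi <- M[-i, -j, drop = FALSE]
    co[i, j] <- (-1)^(i + j) * (mi[1L, 1L] * mi[2L, 2L] - mi[1L, 2L] * mi[2L, 1L])
  }
  t(co)
}
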