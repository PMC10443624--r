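# Shared fixtures, built once per test run and cached (all deterministic).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fx_sphere4 <- function() fixture("sphere4", icosphere(10, 4))
fx_sphere3 <- function() fixture("sphere3", icosphere(10, 3))
fx_torus <- function() fixture("torus", torus_mesh(10, 3, 96, 48))
fx_ellipsoid <- function() fixture("ellipsoid", ellipsoid_mesh(10, 7, 5, 4))

fx_sphere4_curv <- function() fixture("sphere4_curv", principal_curvatures(fx_sphere4()))
fx_torus_curv <- function() fixture("torus_curv", principal_curvatures(fx_torus()))
fx_ellipsoid_curv <- function() fixture("ellipsoid_curv", principal_curvatures(fx_ellipsoid()))

# the default folded phantom (the package's standard study condition)
fx_bumpy <- function() fixture("bumpy", make_bumpy_pair(seed = 1))
fx_bumpy_curv <- function() fixture("bumpy_curv", principal_curvatures(fx_bumpy()$pial))
fx_bumpy_labels <- function() fixture("bumpy_labels", {
  ph <- fx_bumpy()
  si <- smooth_vertex_field(ph$pial, shape_index(fx_bumpy_curv()), 2)
  si <- vertex_field(pmin(1, pmax(-1, as.numeric(si))), ph$pial)
  classify_shapes(si)
})
fx_bumpy_thickness <- function() fixture("bumpy_thickness", {
  ph <- fx_bumpy()
  smooth_vertex_field(ph$pial, cortical_thickness(ph$pial, ph$white), 2,
                      exclude_zero = TRUE)
})

# open square grid patch in the xy plane, n x n vertices, spacing 1 mm
grid_patch <- function(n = 5) {
  xy <- expand.grid(x = seq_len(n) - 1, y = seq_len(n) - 1)
  v <- cbind(xy$x, xy$y, 0)
  id <- function(i, j) (j - 1L) * n + i
  f <- NULL
  for (j in seq_len(n - 1L)) for (i in seq_len(n - 1L)) {
    f <- rbind(f, c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
               c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
  }
  triangle_mesh(v, f, name = "patch")
}

# independent point-to-triangle distance: exhaustive over the projection
# onto the triangle plane and the three edge segments
brute_point_tri_dist <- function(p, A, B, C) {
  M <- cbind(B - A, C - A)
  d <- Inf
  G <- crossprod(M)
  if (abs(det(G)) > 1e-14) {
    uv <- solve(G, crossprod(M, p - A))
    if (uv[1L] >= 0 && uv[2L] >= 0 && sum(uv) <= 1)
      d <- sqrt(sum((A + as.numeric(M %*% uv) - p)^2))
  }
  seg <- function(a, b) {
    t <- sum((p - a) * (b - a)) / sum((b - a)^2)
    t <- min(1, max(0, t))
    sqrt(sum((a + t * (b - a) - p)^2))
  }
  min(d, seg(A, B), seg(B, C), seg(C, A))
}

brute_closest_distance <- function(P, mesh) {
  apply(P, 1L, function(p) {
    min(apply(mesh$faces, 1L, function(f)
      brute_point_tri_dist(p, mesh$vertices[f[1L], ], mesh$vertices[f[2L], ],
                           mesh$vertices[f[3L], ])))
  })
}
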