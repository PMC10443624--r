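test_that("vertex density is the square root of area per vertex", {
  s <- fx_sphere3()
  expect_equal(vertex_density(s), sqrt(surface_area(s) / 642),
               tolerance = 1e-12)
  # dimensional analysis: uniform scaling scales the density linearly
  expect_equal(vertex_density(scale_mesh(s, 3)), 3 * vertex_density(s),
               tolerance = 1e-9)
  degenerate <- triangle_mesh(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)),
                              rbind(1:3), validate = FALSE)
  expect_error(vertex_density(degenerate), "zero area")
})

test_that("remeshing reaches the target count by subdivision and decimation", {
  s3 <- fx_sphere3()                       # 1280 faces
  up <- remesh_to_target(s3, 5120)
  expect_equal(n_faces(up), 5120L)         # exactly one 4x subdivision
  expect_true(is_closed_mesh(up))
  expect_equal(euler_characteristic(up), 2L)
  expect_equal(enclosed_volume(up), 4 / 3 * pi * 1000, tolerance = 0.02)

  down <- remesh_to_target(fixture("sphere4_flat", remesh_to_target(s3, 5120)), 1280)
  expect_gte(n_faces(down), 1216L)
  expect_lte(n_faces(down), 1344L)
  expect_true(is_closed_mesh(down))
  expect_equal(euler_characteristic(down), 2L)
  expect_equal(enclosed_volume(down), 4 / 3 * pi * 1000, tolerance = 0.02)
  # density lands near the sphere prediction for the target vertex count
  vt <- n_vertices(down)
  expect_equal(vertex_density(down), sqrt(4 * pi * 100 / vt), tolerance = 0.1)
  expect_error(remesh_to_target(s3, 10), ">= 20")
})

test_that("laplacian smoothing shrinks closed surfaces and flattens spikes", {
  s <- fx_sphere3()
  expect_identical(laplacian_smooth(s, 0)$vertices, s$vertices)
  sm <- laplacian_smooth(s, 10, 0.5)
  expect_lt(enclosed_volume(sm), enclosed_volume(s))
  expect_identical(sm$faces, s$faces)
  expect_true(all(is.finite(sm$vertices)))
  # single-vertex spike on a plane patch drops after one iteration
  patch <- grid_patch(5)
  center <- which(patch$vertices[, 1] == 2 & patch$vertices[, 2] == 2)
  patch$vertices[center, 3] <- 1
  out <- laplacian_smooth(patch, 1, 0.5)
  expect_lt(out$vertices[center, 3], 1)
  expect_error(laplacian_smooth(s, 1, 1.5), "factor")
})

test_that("taubin smoothing denoises while preserving shape and volume", {
  s <- fx_sphere3()
  expect_identical(taubin_smooth(s, 0)$vertices, s$vertices)
  s4 <- fx_sphere4()
  sm <- taubin_smooth(s4, 20, 0.5, -0.53)
  expect_equal(enclosed_volume(sm), enclosed_volume(s4), tolerance = 0.01)
  # radial noise is attenuated
  set.seed(42)
  noisy <- s
  r <- sqrt(rowSums(s$vertices^2))
  noisy$vertices <- s$vertices * (1 + rnorm(642, 0, 0.01))
  rms_before <- sqrt(mean((sqrt(rowSums(noisy$vertices^2)) - 10)^2))
  den <- taubin_smooth(noisy, 10)
  rms_after <- sqrt(mean((sqrt(rowSums(den$vertices^2)) - 10)^2))
  expect_lt(rms_after, rms_before)
  expect_error(taubin_smooth(s, 5, 0.5, -0.4), "mu")
  expect_error(conditioning_config(taubin_shrink = 0.5, taubin_inflate = -0.3),
               "exceed")
})

test_that("taubin perturbs measured curvature less than laplacian (shrinkage ordering)", {
  s <- fx_sphere4()
  H0 <- 1 / 10
  ht <- mean(abs(principal_curvatures(taubin_smooth(s, 10))$H - H0)) / H0
  hl <- mean(abs(principal_curvatures(laplacian_smooth(s, 10, 0.5))$H - H0)) / H0
  expect_lt(ht, 0.02)
  expect_gt(hl, ht)
})

test_that("field smoothing averages over the one-ring with the expected fixed points", {
  s <- fx_sphere3()
  const <- vertex_field(rep(2.5, 642), s)
  expect_equal(as.numeric(smooth_vertex_field(s, const, 2)), rep(2.5, 642))
  # delta mass spreads and the maximum strictly decreases
  delta <- vertex_field(c(1, rep(0, 641)), s)
  out <- smooth_vertex_field(s, delta, 1)
  expect_lt(max(out), 1)
  expect_gt(sum(as.numeric(out) > 0), 1)
  # rough random field contracts in range
  set.seed(3)
  alt <- vertex_field(runif(642, -1, 1), s)
  sm <- smooth_vertex_field(s, alt, 1)
  expect_lt(diff(range(as.numeric(sm))), diff(range(as.numeric(alt))))
  # global mean preserved on a regular mesh (torus: every vertex degree 6)
  tor <- fx_torus()
  set.seed(7)
  f <- vertex_field(runif(n_vertices(tor)), tor)
  sm2 <- smooth_vertex_field(tor, f, 2)
  expect_equal(mean(as.numeric(sm2)), mean(as.numeric(f)), tolerance = 1e-6)
  # masked zeros stay zero and are left out of the averages
  mix <- vertex_field(c(0, 0, rep(3, 640)), s)
  smz <- smooth_vertex_field(s, mix, 2, exclude_zero = TRUE)
  expect_identical(as.numeric(smz)[1:2], c(0, 0))
  expect_equal(as.numeric(smz)[-(1:2)], rep(3, 640))
})
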