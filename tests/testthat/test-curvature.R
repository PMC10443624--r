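test_that("vertex normals are outward and radial on a sphere, constant on a plane", {
  s <- fx_sphere3()
  n <- vertex_normals(s)
  cosang <- rowSums(n * s$vertices / sqrt(rowSums(s$vertices^2)))
  expect_gt(min(cosang), 0.999)
  # inverted orientation is detected and corrected for closed meshes
  flipped <- s
  flipped$faces <- s$faces[, c(1, 3, 2)]
  n2 <- vertex_normals(flipped)
  expect_gt(min(rowSums(n2 * s$vertices / sqrt(rowSums(s$vertices^2)))), 0.999)
  # plane patch: all normals equal the plane normal
  np <- vertex_normals(grid_patch(4))
  expect_equal(unname(np), matrix(rep(c(0, 0, 1), each = 16), 16, 3),
               tolerance = 1e-12)
})

test_that("discrete curvatures match analytic values on sphere and torus", {
  b <- fx_sphere4_curv()
  expect_gte(mean(abs(b$H - 0.1) / 0.1 < 0.02), 0.99)
  expect_gte(mean(abs(b$K - 0.01) / 0.01 < 0.04), 0.99)
  expect_equal(b$K, b$k1 * b$k2, tolerance = 1e-9)
  expect_equal(b$H, (b$k1 + b$k2) / 2, tolerance = 1e-9)
  # torus outer equator: K = cos(theta) / (r (R + r cos(theta))), theta = 0
  tor <- fx_torus()
  bt <- fx_torus_curv()
  outer <- which(abs(sqrt(rowSums(tor$vertices[, 1:2]^2)) - 13) < 0.05 &
                 abs(tor$vertices[, 3]) < 0.05)
  expect_gt(length(outer), 10)
  expect_equal(mean(bt$K[outer]), 1 / 39, tolerance = 0.05)
})

test_that("curvatures scale as 1/s under uniform scaling", {
  small <- icosphere(10, 3)
  big <- scale_mesh(small, 4)
  bs <- principal_curvatures(small)
  bb <- principal_curvatures(big)
  expect_equal(bb$k1, bs$k1 / 4, tolerance = 1e-6)
  expect_equal(bb$k2, bs$k2 / 4, tolerance = 1e-6)
  expect_equal(bb$K, bs$K / 16, tolerance = 1e-6)
})

test_that("discrete estimator agrees with the analytic oracle on all three surfaces", {
  cases <- list(
    list(mesh = fx_sphere4(), curv = fx_sphere4_curv(),
         kind = "sphere", params = list(R = 10)),
    list(mesh = fx_torus(), curv = fx_torus_curv(),
         kind = "torus", params = list(R = 10, r = 3)),
    list(mesh = fx_ellipsoid(), curv = fx_ellipsoid_curv(),
         kind = "ellipsoid", params = list(a = 10, b = 7, c = 5)))
  for (cs in cases) {
    ora <- analytic_oracle(cs$kind, cs$params, cs$mesh$vertices)
    scale <- pmax(abs(ora$k1), abs(ora$k2))
    ok <- abs(cs$curv$k1 - ora$k1) / scale < 0.05 &
          abs(cs$curv$k2 - ora$k2) / scale < 0.05
    expect_gte(mean(ok), 0.95)
  }
})

test_that("shape index follows the Koenderink formula with both orientations", {
  b <- list(k1 = c(0.1, 0.1, 0.2, 0, -0.1), k2 = c(0.1, -0.1, 0.1, 0, -0.1))
  s_k <- shape_index(b, orientation = "koenderink")
  expect_equal(as.numeric(s_k),
               c(1, 0, (2 / pi) * atan(3), 0, -1), tolerance = 1e-12)
  expect_true(attr(s_k, "flat")[4])
  s_p <- shape_index(b, orientation = "paper")
  expect_equal(as.numeric(s_p), -as.numeric(s_k), tolerance = 1e-12)
})

test_that("classification bins at the published boundaries with ties toward saddle", {
  si <- c(-1, -0.9, -0.875, -0.7, -0.625, -0.5, -0.375, -0.2, -0.125, 0,
          0.125, 0.2, 0.375, 0.5, 0.625, 0.7, 0.875, 0.9, 1)
  lab <- classify_shapes(si)
  expect_equal(as.character(lab$minor),
               c("cap", "cap", "dome", "dome", "ridge", "ridge",
                 "saddle ridge", "saddle ridge", "saddle", "saddle", "saddle",
                 "saddle rut", "saddle rut", "rut", "rut", "trough", "trough",
                 "cup", "cup"))
  expect_equal(as.character(lab$major)[si <= -0.4], rep("convex", 6))
  expect_equal(as.character(lab$major)[si >= 0.4], rep("concave", 6))
  expect_equal(as.character(lab$major)[abs(si) <= 0.375],
               rep("saddle", 7))
  # labels partition the vertex set
  expect_false(anyNA(lab$minor))
  expect_false(anyNA(lab$major))
  expect_error(classify_shapes(c(0.2, 1.4)), "range")
})

test_that("shape classification is invariant under uniform scaling", {
  s <- icosphere(10, 3)
  ph <- fx_bumpy()
  for (mesh in list(s, ph$pial)) {
    lab1 <- classify_shapes(shape_index(principal_curvatures(mesh)))
    lab2 <- classify_shapes(shape_index(principal_curvatures(scale_mesh(mesh, 2.5))))
    expect_identical(lab1$minor, lab2$minor)
  }
})

test_that("a sphere is almost entirely cap and convex in the paper orientation", {
  si <- shape_index(fx_sphere4_curv())
  expect_gte(mean(as.numeric(si) < -0.9), 0.99)
  lab <- classify_shapes(si)
  expect_gte(mean(lab$minor == "cap"), 0.99)
  expect_gte(mean(lab$major == "convex"), 0.99)
})

test_that("shape index tracks the radial deviation on the folded phantom", {
  ph <- fx_bumpy()
  si <- shape_index(fx_bumpy_curv())
  # convex (negative SI) where the surface bulges: strong negative rank
  # correlation with the radial deviation g
  rho <- cor(as.numeric(si), ph$truth$g, method = "spearman")
  expect_lt(rho, -0.5)
})
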