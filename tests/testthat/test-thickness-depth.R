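test_that("closest distances are exact point-to-triangle distances", {
  s <- fx_sphere3()
  d <- closest_distance(c(0, 0, 11), s)
  expect_equal(as.numeric(d), 1, tolerance = 0.01)   # chord-sagitta error
  # a query on a target vertex has distance zero
  expect_equal(as.numeric(closest_distance(s$vertices[5, ], s)), 0)
  # exhaustive all-triangle oracle on random points
  m <- icosphere(5, 2)                               # 320 faces
  set.seed(11)
  P <- matrix(rnorm(300, sd = 4), 100, 3)
  expect_equal(as.numeric(closest_distance(P, m)), brute_closest_distance(P, m),
               tolerance = 1e-9)
})

test_that("concentric spheres recover the analytic shell thickness", {
  ph <- make_sphere_pair(10, 2, 4)
  th <- cortical_thickness(ph$pial, ph$white)
  expect_equal(mean(th), 2, tolerance = 0.02)
  expect_true(all(abs(as.numeric(th) - 2) < 0.04))
  # swapping the roles of pial and white changes the mean by < 2%
  th_sw <- suppressWarnings(cortical_thickness(ph$white, ph$pial))
  expect_equal(mean(th_sw), mean(th), tolerance = 0.02)
})

test_that("the floor rule produces exact zeros and only zeros below the floor", {
  thin <- make_sphere_pair(10, 0.3, 3)
  th <- cortical_thickness(thin$pial, thin$white, thickness_config(floor = 0.5))
  expect_identical(as.numeric(th), rep(0, 642))
  ph <- fx_bumpy()
  th2 <- cortical_thickness(ph$pial, ph$white)
  v <- as.numeric(th2)
  expect_true(all(v == 0 | v >= 0.5))
  expect_error(thickness_config(floor = -1), "floor")
})

test_that("interpenetrating surfaces trigger the geometry warning", {
  ph <- make_sphere_pair(10, 2, 3)
  expect_warning(cortical_thickness(ph$white, ph$pial), "outside")
})

test_that("phantom thickness is recovered within 10% RMS of the generator truth", {
  ph <- fx_bumpy()
  th <- cortical_thickness(ph$pial, ph$white)
  tt <- as.numeric(ph$truth$true_thickness)
  rms <- sqrt(mean((as.numeric(th) - tt)^2)) / mean(tt)
  expect_lt(rms, 0.10)
})

test_that("the alpha wrap of a sphere reproduces the sphere", {
  s <- fx_sphere4()
  w <- build_alpha_surface(s, alpha = 2)
  expect_true(is_closed_mesh(w$mesh))
  expect_equal(euler_characteristic(w$mesh), 2L)
  expect_equal(surface_area(w$mesh), surface_area(s), tolerance = 0.02)
  d <- sulcal_depth(s, w)
  expect_lt(mean(d), 0.05)
})

test_that("the wrap bridges sulci and contains every pial vertex", {
  ph <- fx_bumpy()
  w <- build_alpha_surface(ph$pial, alpha = 15)
  expect_lt(surface_area(w$mesh), surface_area(ph$pial))  # bridging
  # containment: no pial vertex lies more than 0.1 mm outside the wrap
  cd <- closest_distance(ph$pial$vertices, w$mesh)
  fn <- cortimorph:::face_normals(w$mesh)
  side <- rowSums((ph$pial$vertices - attr(cd, "foot")) *
                  fn[attr(cd, "triangle"), ])
  outward <- pmin(as.numeric(cd), pmax(side, 0))
  expect_lte(max(outward), 0.1)
})

test_that("automatic alpha selection is tight, bridging, and scale-equivariant", {
  s <- fx_sphere3()
  a_sphere <- select_alpha(s)
  expect_lte(a_sphere, 2 * vertex_density(s))    # smooth brain: lower bound
  ph <- make_bumpy_pair(seed = 3, subdivisions = 3L)
  a1 <- select_alpha(ph$pial)
  # must exceed half the groove mouth (~ pi R gf / degree) to bridge sulci
  expect_gte(a1, pi * 30 * 0.35 / 8 / 2)
  a2 <- select_alpha(scale_mesh(ph$pial, 2))
  expect_equal(a2, 2 * a1, tolerance = 0.1)
})

test_that("sulcal depth recovers the nominal fold depth in narrow deep sulci", {
  # narrow-mouth pits, high resolution, wrap scale far above the fold width
  ph <- make_bumpy_pair(R = 30, fold_amplitude = 3.5, degree = 8,
                        base_thickness = 1, coupling = 0.2, seed = 1,
                        subdivisions = 5, steepness = 7, groove_fraction = 0.1)
  w <- build_alpha_surface(ph$pial, alpha = 45, voxel = 1.2)
  dep <- sulcal_depth(ph$pial, w)
  bot <- ph$truth$g < -0.95
  expect_equal(median(dep[bot]) / ph$truth$nominal_fold_depth, 1,
               tolerance = 0.15)
  expect_true(all(as.numeric(dep) >= 0))
})

test_that("depth separates gyral crowns from sulcal fundi on the default phantom", {
  ph <- fx_bumpy()
  w <- build_alpha_surface(ph$pial, alpha = 15)
  dep <- sulcal_depth(ph$pial, w)
  lab <- fx_bumpy_labels()
  expect_lt(mean(dep[lab$major == "convex"]), mean(dep[lab$major == "concave"]))
})

test_that("depth is translation-invariant and scales linearly", {
  ph <- make_bumpy_pair(seed = 2, subdivisions = 3L)
  w0 <- build_alpha_surface(ph$pial, alpha = 12)
  d0 <- mean(sulcal_depth(ph$pial, w0))
  moved <- translate_mesh(ph$pial, c(3.25, -1.5, 2.75))
  dm <- mean(sulcal_depth(moved, build_alpha_surface(moved, alpha = 12)))
  expect_equal(dm, d0, tolerance = 5e-3)
  # scaling is exact up to the absolute 0.1 mm containment tolerance, which
  # does not scale with the geometry
  big <- scale_mesh(ph$pial, 2)
  db <- mean(sulcal_depth(big, build_alpha_surface(big, alpha = 24)))
  expect_equal(db, 2 * d0, tolerance = 0.02)
})
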