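test_that("generators are seed-deterministic and sensitive to the seed", {
  a <- make_bumpy_pair(seed = 4, subdivisions = 3L)
  b <- make_bumpy_pair(seed = 4, subdivisions = 3L)
  expect_identical(a$pial$vertices, b$pial$vertices)
  expect_identical(a$white$vertices, b$white$vertices)
  expect_identical(as.numeric(a$truth$true_thickness),
                   as.numeric(b$truth$true_thickness))
  c3 <- make_bumpy_pair(seed = 5, subdivisions = 3L)
  expect_false(identical(a$pial$vertices, c3$pial$vertices))
})

test_that("every phantom pair is closed, oriented, with white strictly inside pial", {
  for (ph in list(make_sphere_pair(10, 2, 3),
                  make_bumpy_pair(seed = 6, subdivisions = 3L),
                  fx_bumpy())) {
    for (m in list(ph$pial, ph$white)) {
      expect_true(is_closed_mesh(m))
      expect_true(is_oriented_mesh(m))
      expect_equal(euler_characteristic(m), 2L)
    }
    expect_true(all(as.numeric(ph$truth$true_thickness) > 0))
    # white inside pial: signed distance of white vertices is negative
    cd <- closest_distance(ph$white$vertices, ph$pial)
    fn <- cortimorph:::face_normals(ph$pial)
    side <- rowSums((ph$white$vertices - attr(cd, "foot")) *
                    fn[attr(cd, "triangle"), ])
    expect_true(all(side < 1e-6 | as.numeric(cd) < 1e-6))
  }
})

test_that("degenerate and infeasible phantom parameters are rejected", {
  expect_error(make_sphere_pair(10, 12), "thickness")
  expect_error(make_bumpy_pair(fold_amplitude = 15), "R/3")
  expect_error(make_bumpy_pair(base_thickness = 0.1, coupling = 0.4),
               "coupling")
  # zero amplitude degenerates to the concentric-sphere pair
  flat <- make_bumpy_pair(R = 10, fold_amplitude = 0, base_thickness = 2,
                          subdivisions = 3L)
  ref <- make_sphere_pair(10, 2, 3L)
  expect_equal(flat$pial$vertices, ref$pial$vertices)
  expect_equal(flat$white$vertices, ref$white$vertices)
})

test_that("zero coupling yields a unit thickness ratio through the pipeline", {
  ph <- make_bumpy_pair(coupling = 0, seed = 1)
  si <- smooth_vertex_field(ph$pial, shape_index(principal_curvatures(ph$pial)), 2)
  lab <- classify_shapes(vertex_field(pmin(1, pmax(-1, as.numeric(si))), ph$pial))
  th <- smooth_vertex_field(ph$pial, cortical_thickness(ph$pial, ph$white), 2,
                            exclude_zero = TRUE)
  expect_equal(thickness_ratio(th, lab), 1, tolerance = 0.03)
})

test_that("isometric families are exact coordinate scalings", {
  base <- make_bumpy_pair(seed = 7, subdivisions = 3L)
  fam <- make_isometric_family(base, c(1, 2, 4))
  expect_identical(fam[[1]]$pial$vertices, base$pial$vertices)
  expect_equal(fam[[3]]$pial$vertices, 4 * base$pial$vertices, tolerance = 1e-15)
  expect_equal(as.numeric(fam[[2]]$truth$true_thickness),
               2 * as.numeric(base$truth$true_thickness), tolerance = 1e-15)
  expect_equal(fam[[2]]$truth$nominal_fold_depth,
               2 * base$truth$nominal_fold_depth, tolerance = 1e-15)
  expect_error(make_isometric_family(base, c(1, -2)), "positive")
})

test_that("allometric cohorts carry the prescribed exponents", {
  co <- make_allometric_cohort(n_species = 6, exponents = list(thickness = 0.5,
                                                               amplitude = 0.5),
                               noise = 0, seed = 2, subdivisions = 2L)
  fit <- allometric_fit(co$table$area, co$table$thickness, "loglog")
  expect_equal(fit$slope, 0.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # a shallow exponent is flagged against the isometric reference
  co2 <- make_allometric_cohort(n_species = 6, exponents = list(thickness = 0.2,
                                                                amplitude = 0.5),
                                noise = 0.02, seed = 2, subdivisions = 2L)
  fit2 <- allometric_fit(co2$table$area, co2$table$thickness, "loglog")
  expect_equal(isometry_check(fit2, 0.5), "shallower")
  # bit-identical reproduction from the same seed
  co3 <- make_allometric_cohort(n_species = 6, noise = 0, seed = 2,
                                subdivisions = 2L)
  expect_identical(co$table$area, co3$table$area)
  expect_identical(co$phantoms[[3]]$pial$vertices, co3$phantoms[[3]]$pial$vertices)
})

test_that("the analytic oracle returns closed-form curvatures", {
  s <- fx_sphere4()
  ora <- analytic_oracle("sphere", list(R = 10), s$vertices)
  expect_equal(ora$K, rep(0.01, nrow(s$vertices)), tolerance = 1e-9)
  expect_equal(ora$H, rep(0.1, nrow(s$vertices)), tolerance = 1e-9)
  expect_equal(ora$SI, rep(-1, nrow(s$vertices)))      # paper orientation
  # torus outer equator
  p_outer <- matrix(c(13, 0, 0), 1)
  ot <- analytic_oracle("torus", list(R = 10, r = 3), p_outer)
  expect_equal(ot$K, 1 / 39, tolerance = 1e-9)
  # ellipsoid tips are umbilic: |SI| = 1
  tips <- rbind(c(10, 0, 0), c(-10, 0, 0))
  oe <- analytic_oracle("ellipsoid", list(a = 10, b = 7, c = 7), tips)
  expect_equal(abs(oe$SI), c(1, 1), tolerance = 1e-6)
  expect_error(analytic_oracle("sphere", list(R = 10), matrix(c(0, 0, 14), 1)),
               "off the sphere")
})
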