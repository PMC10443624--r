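test_that("area and volume match closed forms on primitive solids", {
  cube <- box_mesh(1)
  expect_equal(surface_area(cube), 6)
  expect_equal(enclosed_volume(cube), 1)
  s <- fx_sphere4()
  expect_equal(surface_area(s), 4 * pi * 100, tolerance = 0.01)
  expect_equal(enclosed_volume(s), 4 / 3 * pi * 1000, tolerance = 0.015)
  # area scales with s^2, translation leaves volume unchanged
  expect_equal(surface_area(scale_mesh(cube, 3)), 54, tolerance = 1e-12)
  expect_equal(enclosed_volume(translate_mesh(s, c(5, -7, 11))),
               enclosed_volume(s), tolerance = 1e-9)
  expect_error(enclosed_volume(grid_patch(3)), "closed")
})

test_that("gyrification index is total over exposed area with wrap sanity checks", {
  expect_equal(gyrification_index(200, 100), 2)
  expect_equal(gyrification_index(100, 100), 1)
  expect_warning(gyrification_index(100, 110), "exceeds")
  s <- fx_sphere4()
  w <- build_alpha_surface(s, alpha = 2)
  expect_equal(gyrification_index(surface_area(s), surface_area(w$mesh)), 1,
               tolerance = 0.02)
  # dimensionless: identical under uniform scaling
  expect_equal(gyrification_index(200 * 9, 100 * 9), 2)
})

test_that("folding amplitude is the vertex-level mean depth", {
  s <- fx_sphere3()
  d <- vertex_field(rep(c(0, 1, 2), length.out = 642), s, "mm")
  expect_equal(folding_amplitude(d), mean(rep(c(0, 1, 2), length.out = 642)))
  expect_error(folding_amplitude(vertex_field(rep(-1, 642), s)), "non-negative")
})

test_that("thickness ratio contrasts convex and concave means, excluding zeros", {
  lab <- fx_bumpy_labels()
  n <- length(lab$major)
  uniform <- rep(2, n)
  expect_equal(thickness_ratio(uniform, lab), 1)
  # floored zeros are excluded from both class means
  zeroed <- uniform
  zeroed[seq(1, n, by = 7)] <- 0
  expect_equal(thickness_ratio(zeroed, lab), 1)
  allcap <- classify_shapes(rep(-1, 5))
  expect_error(thickness_ratio(rep(2, 5), allcap), "concave")
})

test_that("injected convex/concave means near 3.0 and 2.4 give a ratio near 1.25", {
  # a 3 mm cortex needs proportionally gentler fold curvature; same folding
  # pattern at 1.5x the scale
  ph <- make_bumpy_pair(R = 45, fold_amplitude = 6, base_thickness = 2.7,
                        coupling = 0.6, seed = 1)
  si <- smooth_vertex_field(ph$pial, shape_index(principal_curvatures(ph$pial)), 2)
  lab <- classify_shapes(vertex_field(pmin(1, pmax(-1, as.numeric(si))), ph$pial))
  th <- smooth_vertex_field(ph$pial, cortical_thickness(ph$pial, ph$white), 2,
                            exclude_zero = TRUE)
  expect_equal(thickness_ratio(th, lab), 1.25, tolerance = 0.05)
})

test_that("the subject record satisfies its invariants and the law of total mean", {
  ph <- fx_bumpy()
  lab <- fx_bumpy_labels()
  th <- fx_bumpy_thickness()
  w <- build_alpha_surface(ph$pial, alpha = 15)
  dep <- sulcal_depth(ph$pial, w)
  rec <- summarize_subject(ph$pial, ph$white, w, th, dep, lab,
                           species = "phantom", subject_id = "p1")
  expect_gte(rec$gi, 1 - 0.02)
  expect_gt(rec$total_area, 0)
  expect_gt(rec$volume, 0)
  expect_gt(rec$thickness_ratio, 1)
  # mean thickness equals the count-weighted mean of the 3-class means
  tab <- rec$per_shape_thickness
  maj <- tab[tab$scheme == "major", ]
  expect_equal(rec$mean_thickness, sum(maj$mean * maj$n) / sum(maj$n),
               tolerance = 1e-9)
  min9 <- tab[tab$scheme == "minor", ]
  expect_equal(sum(min9$n), sum(as.numeric(th) > 0))
  # two identical hemispheres give the same metrics as one
  both <- combine_meshes(ph$pial, ph$pial)
  both_w <- combine_meshes(ph$white, ph$white)
  lab2 <- list(minor = rep(lab$minor, 2), major = rep(lab$major, 2))
  class(lab2) <- "shape_labels"
  rec2 <- summarize_subject(both, both_w, w,
                            vertex_field(rep(as.numeric(th), 2), both, "mm"),
                            vertex_field(rep(as.numeric(dep), 2), both, "mm"),
                            lab2, species = "phantom", subject_id = "p2")
  expect_equal(rec2$mean_thickness, rec$mean_thickness, tolerance = 1e-12)
  expect_equal(rec2$thickness_ratio, rec$thickness_ratio, tolerance = 1e-12)
  expect_equal(rec2$folding_amplitude, rec$folding_amplitude, tolerance = 1e-12)
})

test_that("isometric scaling gives exact power laws in the truth fields", {
  base <- make_bumpy_pair(seed = 5, subdivisions = 3L)
  fam <- make_isometric_family(base, c(1, 1.5, 2, 3, 4))
  areas <- vapply(fam, function(p) surface_area(p$pial), numeric(1))
  scales <- c(1, 1.5, 2, 3, 4)
  expect_lt(diff(range(areas / scales^2)) / mean(areas / scales^2), 1e-6)
  vols <- vapply(fam, function(p) enclosed_volume(p$pial), numeric(1))
  expect_lt(diff(range(vols / scales^3)) / mean(vols / scales^3), 1e-6)
  t_means <- vapply(fam, function(p) mean(p$truth$true_thickness), numeric(1))
  fit <- allometric_fit(areas, t_means, "loglog")
  expect_equal(fit$slope, 0.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})
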