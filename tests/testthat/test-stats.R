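test_that("shape-binned statistics aggregate and conserve counts", {
  lab <- fx_bumpy_labels()
  n <- length(lab$major)
  uniform <- rep(1.7, n)
  tab <- shape_binned_stats(uniform, lab)
  expect_true(all(abs(tab$mean[tab$n > 0] - 1.7) < 1e-12))
  th <- fx_bumpy_thickness()
  tab2 <- shape_binned_stats(th, lab)
  nz <- sum(as.numeric(th) != 0)
  expect_equal(sum(tab2$n[tab2$scheme == "minor"]), nz)
  expect_equal(sum(tab2$n[tab2$scheme == "major"]), nz)
  # thickness increases from concave through saddle to convex
  maj <- tab2[tab2$scheme == "major", ]
  m <- setNames(maj$mean, maj$class)
  expect_gt(m["convex"], m["saddle"])
  expect_gt(m["saddle"], m["concave"])
})

test_that("kernel density profiles are calibrated and normalized", {
  set.seed(99)
  x <- rnorm(10000)
  kd <- kde_profile(x)
  at0 <- kd$density[which.min(abs(kd$x))]
  expect_equal(at0, dnorm(0), tolerance = 0.05)
  mass <- sum(kd$density) * diff(kd$x[1:2])
  expect_equal(mass, 1, tolerance = 0.01)
  # separated mixture is bimodal: two interior local maxima
  y <- c(rnorm(5000, -4), rnorm(5000, 4))
  kd2 <- kde_profile(y)
  d <- kd2$density
  peaks <- which(diff(sign(diff(d))) == -2) + 1L
  expect_equal(length(peaks), 2L)
  expect_error(kde_profile(1:5), "10")
  expect_warning(kde_profile(rep(2, 50)), "variance")
})

test_that("welch contrast and Cohen's d match construction and brute force", {
  a <- c(1.1, 2.3, 0.7, 1.9, 2.2)
  b <- c(2.0, 2.8, 1.4, 3.1)
  ct <- shape_contrast(a, b, "A", "B")
  # brute-force Welch t and pooled-sd d
  se <- sqrt(var(a) / 5 + var(b) / 4)
  t_ref <- (mean(a) - mean(b)) / se
  sp <- sqrt((4 * var(a) + 3 * var(b)) / 7)
  d_ref <- (mean(a) - mean(b)) / sp
  expect_equal(ct$t, t_ref, tolerance = 1e-10)
  expect_equal(ct$d, d_ref, tolerance = 1e-10)
  expect_equal(ct$p, t.test(a, b)$p.value, tolerance = 1e-10)
  # identical groups: d = 0, p = 1
  eq <- shape_contrast(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$d, 0)
  expect_equal(eq$p, 1)
  # swap antisymmetry
  sw <- shape_contrast(b, a, "B", "A")
  expect_equal(sw$d, -ct$d)
  expect_equal(sw$t, -ct$t)
  expect_equal(sw$p, ct$p)
  # construction d = 0.3 / 0.5 = 0.6 at large n
  set.seed(123)
  g1 <- rnorm(10000, 3.0, 0.5)
  g2 <- rnorm(10000, 2.7, 0.5)
  expect_equal(shape_contrast(g1, g2)$d, 0.6, tolerance = 0.05)
})

test_that("local correlation behaves as Pearson r over non-floored vertices", {
  x <- c(0.3, 1.2, 2.2, 3.1, 4.5, 5.2)
  expect_equal(local_correlation(x, x)$r, 1)
  expect_equal(local_correlation(x, -x)$r, -1)
  expect_error(local_correlation(x, rep(1, 6)), "constant")
  # the phantom couples thickness to shape: thick where SI is negative
  si <- shape_index(fx_bumpy_curv())
  th <- fx_bumpy_thickness()
  expect_lt(local_correlation(th, si)$r, 0)
})

test_that("allometric fits recover exponents and flag bad domains", {
  x <- 1:10
  f <- allometric_fit(x, 2 * x^1.5, "loglog")
  expect_equal(f$slope, 1.5, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_true(f$ci95_slope[1] <= f$slope && f$slope <= f$ci95_slope[2])
  fc <- allometric_fit(x, rep(5, 10), "loglog")
  expect_equal(fc$slope, 0, tolerance = 1e-12)
  # known exponent under multiplicative noise lands inside the CI
  set.seed(17)
  xs <- exp(runif(50, 0, 4))
  ys <- xs^0.5 * exp(rnorm(50, 0, 0.05))
  fn <- allometric_fit(xs, ys, "loglog")
  expect_gte(0.5, fn$ci95_slope[1])
  expect_lte(0.5, fn$ci95_slope[2])
  expect_error(allometric_fit(c(-1, 2, 3), 1:3, "loglog"), "non-positive x")
  expect_error(allometric_fit(1:3, c(1, -2, 3), "loglog"), "non-positive y")
  expect_error(allometric_fit(1:2, 1:2), "n >= 3")
  # semilog: slope in units of y per decade of x
  fs <- allometric_fit(c(10, 100, 1000), c(1, 2, 3), "semilog")
  expect_equal(fs$slope, 1, tolerance = 1e-12)
})

test_that("isometry verdicts report the CI side", {
  f <- list(mode = "loglog", slope = 0.5, ci95_slope = c(0.45, 0.55))
  expect_equal(isometry_check(f, 0.5), "consistent")
  expect_equal(isometry_check(f, 0.4), "steeper")
  expect_equal(isometry_check(f, 0.6), "shallower")
  expect_error(isometry_check(list(mode = "semilog"), 1), "loglog")
})

test_that("age trends detect linear thinning and nothing in permuted data", {
  ages <- seq(5, 60, by = 5)
  vals <- 3.0 - 0.01 * ages
  tr <- age_trend(ages, vals)
  expect_equal(tr$slope, -0.01, tolerance = 1e-12)
  expect_lt(tr$p_slope, 1e-10)
  # adding a constant leaves the slope unchanged
  expect_equal(age_trend(ages, vals + 7)$slope, tr$slope, tolerance = 1e-12)
  set.seed(31)
  perm <- age_trend(ages, sample(vals))
  expect_lt(abs(perm$slope), 0.01)
  expect_gt(perm$p_slope, 0.05)
  expect_error(age_trend(rep(10, 5), 1:5), "constant")
})

test_that("reciprocal exponents reproduce the published arithmetic exactly", {
  expect_identical(reciprocal_exponent(0.82), 1.22)
  expect_identical(reciprocal_exponent(1.16), 0.86)
  expect_error(reciprocal_exponent(0), "zero")
})
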