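#' Concentric-sphere pial/white phantom
#'
#' Icospheres of radii `R` (pial) and `R - thickness` (white) with exact
#' ground truth: constant thickness, `K = 1/R^2`, `H = 1/R` on the pial
#' surface.
#'
#' @param R pial radius in mm.
#' @param thickness shell thickness in mm (0 < thickness < R).
#' @param subdivisions icosphere subdivision level.
#' @return object of class `phantom_pair`: list with `pial`, `white`, `truth`
#'   (a `phantom_truth` list).
#' @export
make_sphere_pair <- function(R = 10, thickness = 2, subdivisions = 4L) {
  if (thickness <= 0 || thickness >= R) stop("need 0 < thickness < R")
  pial <- icosphere(R, subdivisions)
  pial$name <- "pial"
  white <- icosphere(R - thickness, subdivisions)
  white$name <- "white"
  truth <- structure(list(
    true_thickness = vertex_field(rep(thickness, n_vertices(pial)), pial, "mm"),
    true_K = rep(1 / R^2, n_vertices(pial)),
    true_H = rep(1 / R, n_vertices(pial)),
    g = rep(0, n_vertices(pial)),
    nominal_fold_depth = 0, nominal_fold_count = 0L,
    scale = 1, thickness_coupling = 0, seed = NA_integer_),
    class = "phantom_truth")
  structure(list(pial = pial, white = white, truth = truth),
            class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat("phantom_pair: ", n_vertices(x$pial), " vertices/surface, fold depth ",
      signif(x$truth$nominal_fold_depth, 3), " mm, coupling ",
      x$truth$thickness_coupling, " mm\n", sep = "")
  invisible(x)
}

# real spherical harmonics of a single degree l, random orders, unit max
random_band_harmonic <- function(l, theta, phi, seed) {
  set.seed(seed)
  coef <- rnorm(2L * l + 1L)
  P <- pracma::legendre(l, cos(theta))   # (l+1) x n, rows m = 0..l
  if (is.null(dim(P))) P <- matrix(P, nrow = l + 1L)
  Y <- coef[1L] * sqrt((2 * l + 1) / (4 * pi)) * P[1L, ]
  for (m in seq_len(l)) {
    N <- sqrt((2 * l + 1) / (2 * pi) * exp(lfactorial(l - m) - lfactorial(l + m)))
    Y <- Y + N * P[m + 1L, ] * (coef[2L * m] * cos(m * phi) +
                                coef[2L * m + 1L] * sin(m * phi))
  }
  Y / max(abs(Y))
}

#' Folded-sphere pial/white phantom with shape-coupled thickness
#'
#' The pial surface is a sphere of radius `R` carved by inward sulcal
#' grooves: a random band-limited spherical-harmonic field `Y` of degree
#' `degree` (normalized to `max |Y| = 1`) is passed through a sigmoid,
#' `radius = R - a * (1 - tanh(steepness * Y) / tanh(steepness))`, so gyral
#' crowns form a near-uniform envelope at radius `R`, sulcal fundi plateau
#' near `R - 2a`, and the walls between them are steep — the geometry a
#' tight wrap can bridge flush, like the cortex. The white surface is offset
#' inward along the pial normal by the thickness field
#' `t = base_thickness + (coupling / 2) * g`, with `g` the normalized radial
#' deviation (+1 on crowns, -1 in fundi): crowns are uniformly thick and
#' fundi uniformly thin, with a gradient across the walls. All ground truth
#' is stored.
#'
#' @param R envelope (crown) radius, mm.
#' @param fold_amplitude half fold depth `a`, mm (fundi sit near `R - 2a`;
#'   a < R/3).
#' @param degree spherical-harmonic degree (fold wavelength ~ 2 pi R /
#'   degree).
#' @param base_thickness mean cortical thickness `t0`, mm.
#' @param coupling injected convex-minus-concave thickness difference, mm
#'   (t0 > coupling/2).
#' @param seed RNG seed; generation is fully deterministic given it.
#' @param subdivisions icosphere subdivision level.
#' @param steepness sigmoid gain shaping the groove walls.
#' @param groove_fraction area fraction of the surface carved into grooves.
#' @return a `phantom_pair` (see [make_sphere_pair()]).
#' @export
make_bumpy_pair <- function(R = 30, fold_amplitude = 4, degree = 8L,
                            base_thickness = 1.6, coupling = 0.4, seed = 1L,
                            subdivisions = 4L, steepness = 2.5,
                            groove_fraction = 0.35) {
  if (fold_amplitude < 0 || fold_amplitude >= R / 3)
    stop("need 0 <= fold_amplitude < R/3")
  if (base_thickness <= coupling / 2)
    stop("need base_thickness > coupling/2")
  if (fold_amplitude == 0)
    return(make_sphere_pair(R, base_thickness, subdivisions))
  unit <- icosphere(1, subdivisions)
  u <- unit$vertices
  theta <- acos(pmin(1, pmax(-1, u[, 3L])))
  phi <- atan2(u[, 2L], u[, 1L])
  Y <- random_band_harmonic(degree, theta, phi, seed)
  # rank-uniformize the harmonic field so crowns and fundi occupy a fixed
  # area fraction, then squash through a sigmoid: broad plateaus at the
  # envelope (crowns) and at depth (fundi), steep walls between
  Yu <- 2 * rank(Y) / (length(Y) + 1) - 1
  y0 <- 2 * groove_fraction - 1          # grooves occupy Yu < y0
  sig <- function(k) {
    s <- tanh(k * (Yu - y0))
    lo <- tanh(k * (-1 - y0)); hi <- tanh(k * (1 - y0))
    2 * (s - lo) / (hi - lo) - 1
  }
  g_geo <- sig(steepness)
  dev <- fold_amplitude * (g_geo - 1)    # 0 at crowns, -2a at fundi
  r <- R + dev
  pial <- unit
  pial$vertices <- u * r
  pial$name <- "pial"
  # thickness saturates faster than the geometry so crowns/fundi carry the
  # full coupling well past the class boundaries (plateau thickness pattern)
  g <- sig(2 * steepness)
  t <- base_thickness + (coupling / 2) * g
  nrm <- vertex_normals(pial)
  white <- pial
  white$vertices <- pial$vertices - nrm * t
  white$name <- "white"
  # reject self-intersecting constructions
  if (signed_volume(white) <= 0)
    stop("white surface self-intersects; reduce fold_amplitude, coupling or base_thickness")
  dw <- closest_distance(white$vertices, pial)
  fn <- face_normals(pial)
  side <- rowSums((white$vertices - attr(dw, "foot")) *
                    fn[attr(dw, "triangle"), , drop = FALSE])
  if (any(side > 1e-6 & as.numeric(dw) > 1e-6))
    stop("white surface pokes through the pial surface; ",
         "reduce fold_amplitude, coupling or base_thickness")
  truth <- structure(list(
    true_thickness = vertex_field(t, pial, "mm"),
    true_K = NULL, true_H = NULL,
    g = g,
    nominal_fold_depth = as.numeric(quantile(r, 0.95) - quantile(r, 0.05)),
    nominal_fold_count = as.integer(degree),
    scale = 1, thickness_coupling = coupling, seed = seed),
    class = "phantom_truth")
  structure(list(pial = pial, white = white, truth = truth),
            class = "phantom_pair")
}

#' Isometrically scaled family of phantoms
#'
#' Multiplies all coordinates of both surfaces of the base phantom by each
#' scale; ground-truth thickness and fold depth scale linearly, areas with
#' the square, volume with the cube, and GI/shape are unchanged.
#'
#' @param base a `phantom_pair`.
#' @param scales positive scale factors.
#' @return list of `phantom_pair`s.
#' @export
make_isometric_family <- function(base, scales = c(1, 1.5, 2, 3, 4)) {
  if (any(scales <= 0)) stop("scales must be positive")
  lapply(scales, function(s) {
    p <- base
    p$pial <- scale_mesh(p$pial, s)
    p$white <- scale_mesh(p$white, s)
    tr <- p$truth
    tr$true_thickness <- vertex_field(as.numeric(tr$true_thickness) * s,
                                      p$pial, "mm")
    if (!is.null(tr$true_K)) tr$true_K <- tr$true_K / s^2
    if (!is.null(tr$true_H)) tr$true_H <- tr$true_H / s
    tr$nominal_fold_depth <- tr$nominal_fold_depth * s
    tr$scale <- tr$scale * s
    p$truth <- tr
    p
  })
}

#' Synthetic cross-species cohort with prescribed allometric exponents
#'
#' Builds `n_species` bumpy phantoms whose total pial areas span
#' `area_range` (log-spaced) and whose base thickness and fold amplitude
#' follow prescribed power laws of the realized area, with multiplicative
#' lognormal noise. Used for exponent-recovery tests. Parameter combinations
#' that would self-intersect are skipped with a warning.
#'
#' @param n_species number of species.
#' @param area_range range of total pial areas, mm^2.
#' @param exponents list with `thickness` and `amplitude` exponents vs total
#'   area (isometric values: 0.5 and 0.5).
#' @param noise lognormal sigma of the multiplicative noise (0 = exact).
#' @param seed RNG seed.
#' @param degree harmonic degree of the folding.
#' @param subdivisions icosphere subdivision level.
#' @return list with `phantoms` (list of `phantom_pair`), `table`
#'   (data.frame: species, area, thickness, amplitude, radius, seed).
#' @export
make_allometric_cohort <- function(n_species = 8L, area_range = c(1500, 60000),
                                   exponents = list(thickness = 0.5, amplitude = 0.5),
                                   noise = 0, seed = 1L, degree = 4L,
                                   subdivisions = 3L) {
  stopifnot(n_species >= 3L)
  areas_target <- exp(seq(log(area_range[1L]), log(area_range[2L]),
                          length.out = n_species))
  set.seed(seed)
  noise_t <- exp(rnorm(n_species, 0, noise))
  noise_a <- exp(rnorm(n_species, 0, noise))
  A_ref <- sqrt(prod(area_range))
  t_ref <- 2.0
  a_ref <- 1.5
  phantoms <- list()
  rows <- list()
  skipped <- 0L
  for (i in seq_len(n_species)) {
    R_i <- sqrt(areas_target[i] / (4 * pi))
    amp_i <- a_ref * (areas_target[i] / A_ref)^exponents$amplitude * noise_a[i]
    # build the pial first, measure the realized area, then set thickness
    p0 <- try(make_bumpy_pair(R = R_i, fold_amplitude = min(amp_i, 0.32 * R_i),
                              degree = degree, base_thickness = 0.18 * R_i,
                              coupling = 0, seed = seed + i,
                              subdivisions = subdivisions), silent = TRUE)
    if (inherits(p0, "try-error")) { skipped <- skipped + 1L; next }
    A_i <- surface_area(p0$pial)
    t_i <- t_ref * (A_i / A_ref)^exponents$thickness * noise_t[i]
    p <- try(make_bumpy_pair(R = R_i, fold_amplitude = min(amp_i, 0.32 * R_i),
                             degree = degree, base_thickness = t_i,
                             coupling = 0, seed = seed + i,
                             subdivisions = subdivisions), silent = TRUE)
    if (inherits(p, "try-error")) { skipped <- skipped + 1L; next }
    phantoms[[length(phantoms) + 1L]] <- p
    rows[[length(rows) + 1L]] <- data.frame(
      species = sprintf("species%02d", i), area = A_i, thickness = t_i,
      amplitude = p$truth$nominal_fold_depth, radius = R_i, seed = seed + i)
  }
  if (skipped > 0L)
    warning(skipped, " species skipped (infeasible parameter combination)")
  list(phantoms = phantoms, table = do.call(rbind, rows))
}
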