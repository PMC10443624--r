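#' Per-shape means, SDs, and counts of a vertex measure
#'
#' Aggregates a per-vertex measure (thickness, depth) over the 9 minor and 3
#' major shape classes. Floored zeros are excluded when `exclude_zeros` is on
#' (the default, matching the thickness convention).
#'
#' @param field a [vertex_field()] or numeric vector.
#' @param labels a `shape_labels` object of the same length.
#' @param exclude_zeros drop exact zeros before aggregation.
#' @return data.frame with columns `scheme` ("minor"/"major"), `class`,
#'   `mean`, `sd`, `n`; counts within a scheme sum to the number of retained
#'   vertices.
#' @export
shape_binned_stats <- function(field, labels, exclude_zeros = TRUE) {
  x <- as.numeric(field)
  if (length(x) != length(labels$minor))
    stop("field and labels are not aligned")
  keep <- if (exclude_zeros) x != 0 else rep(TRUE, length(x))
  agg <- function(groups, scheme) {
    g <- groups[keep]
    v <- x[keep]
    data.frame(scheme = scheme,
               class = levels(g),
               mean = as.numeric(tapply(v, g, mean)),
               sd = as.numeric(tapply(v, g, sd)),
               n = as.integer(table(g)),
               row.names = NULL)
  }
  rbind(agg(labels$minor, "minor"), agg(labels$major, "major"))
}

#' Gaussian kernel density profile
#'
#' Density of a sample evaluated on an explicit grid with a Gaussian kernel;
#' bandwidth defaults to Scott's rule `sd(x) * n^(-1/5)`.
#'
#' @param samples numeric sample (n >= 10).
#' @param grid evaluation points; defaults to 512 points spanning the sample
#'   range plus 4 bandwidths.
#' @param bw kernel bandwidth; `NULL` for Scott's rule.
#' @return data.frame with columns `x`, `density`.
#' @export
kde_profile <- function(samples, grid = NULL, bw = NULL) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 10L) stop("kde_profile() needs at least 10 samples")
  s <- sd(samples)
  if (is.null(bw)) bw <- s * length(samples)^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) {
    warning("zero-variance sample: returning a narrow spike kernel")
    bw <- max(abs(mean(samples)), 1) * 1e-3
  }
  if (is.null(grid))
    grid <- seq(min(samples) - 4 * bw, max(samples) + 4 * bw, length.out = 512L)
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, mean = samples, sd = bw)),
                 numeric(1))
  data.frame(x = grid, density = dens)
}

#' Welch contrast between two vertex-sample groups
#'
#' Welch two-sample t test plus Cohen's d with pooled standard deviation;
#' `d` carries the sign of `mean(a) - mean(b)`.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param class_a,class_b group labels for the record.
#' @return object of class `shape_contrast`: list with `class_a`, `class_b`,
#'   `mean_a`, `mean_b`, `t`, `p`, `d`, `n_a`, `n_b`.
#' @export
shape_contrast <- function(a, b, class_a = "a", class_b = "b") {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  d <- if (sp2 > 0) (mean(a) - mean(b)) / sqrt(sp2) else 0
  if (sp2 > 0) {
    tt <- t.test(a, b)
    tval <- unname(tt$statistic); p <- tt$p.value
  } else {
    tval <- 0; p <- 1
  }
  structure(list(class_a = class_a, class_b = class_b,
                 mean_a = mean(a), mean_b = mean(b),
                 t = tval, p = p, d = d, n_a = na, n_b = nb),
            class = "shape_contrast")
}

#' @export
print.shape_contrast <- function(x, ...) {
  cat(sprintf("%s vs %s: mean %.4g vs %.4g, t = %.3g, p = %.3g, d = %.3g\n",
              x$class_a, x$class_b, x$mean_a, x$mean_b, x$t, x$p, x$d))
  invisible(x)
}

#' Pearson correlation between two aligned vertex fields
#'
#' @param field_a,field_b aligned [vertex_field()]s or numeric vectors.
#' @param exclude_zeros drop vertices where either field is exactly zero
#'   (floored thickness).
#' @return list with `r`, `p`, `n`.
#' @export
local_correlation <- function(field_a, field_b, exclude_zeros = TRUE) {
  a <- as.numeric(field_a); b <- as.numeric(field_b)
  if (length(a) != length(b)) stop("fields are not aligned")
  keep <- if (exclude_zeros) a != 0 & b != 0 else rep(TRUE, length(a))
  a <- a[keep]; b <- b[keep]
  if (sd(a) == 0 || sd(b) == 0)
    stop("correlation undefined for a constant field")
  ct <- cor.test(a, b)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Allometric scaling fit
#'
#' Least-squares line of `log10(y)` on `log10(x)` (`mode = "loglog"`, for
#' dimensioned quantities: the slope is the power-law exponent) or of `y` on
#' `log10(x)` (`mode = "semilog"`, for the dimensionless gyrification index).
#' The 95% CI of the slope comes from the t distribution.
#'
#' @param x positive predictor values (e.g. total surface area).
#' @param y response values; must be positive under `loglog`.
#' @param mode `"loglog"` or `"semilog"`.
#' @param x_name,y_name labels for the record.
#' @return object of class `allometric_fit`: list with `mode`, `slope`,
#'   `intercept`, `r_squared`, `p_slope`, `ci95_slope`, `n`, `x_name`,
#'   `y_name`.
#' @export
allometric_fit <- function(x, y, mode = c("loglog", "semilog"),
                           x_name = "x", y_name = "y") {
  mode <- match.arg(mode)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("allometric_fit() needs n >= 3")
  if (any(x <= 0))
    stop("non-positive x value(s) at position(s): ",
         paste(head(which(x <= 0)), collapse = ", "))
  if (mode == "loglog" && any(y <= 0))
    stop("non-positive y value(s) under loglog at position(s): ",
         paste(head(which(y <= 0)), collapse = ", "))
  lx <- log10(x)
  ly <- if (mode == "loglog") log10(y) else y
  fit <- lm(ly ~ lx)
  sm <- suppressWarnings(summary(fit))  # noiseless fits trip a perfect-fit warning
  r2 <- sm$r.squared
  if (!is.finite(r2))  # constant response: zero residuals, define R^2 = 1
    r2 <- if (sum(stats::residuals(fit)^2) < 1e-20) 1 else 0
  ci <- suppressWarnings(suppressMessages(confint(fit, "lx", level = 0.95)))
  slope <- unname(coef(fit)[2L])
  p_slope <- if (nrow(sm$coefficients) > 1L && ncol(sm$coefficients) >= 4L)
    sm$coefficients[2L, 4L] else NA_real_
  structure(list(mode = mode, slope = slope,
                 intercept = unname(coef(fit)[1L]),
                 r_squared = r2,
                 p_slope = p_slope,
                 ci95_slope = as.numeric(ci),
                 n = length(x), x_name = x_name, y_name = y_name),
            class = "allometric_fit")
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("%s fit of %s vs %s (n = %d): slope %.4g [%.4g, %.4g], R^2 = %.3f\n",
              x$mode, x$y_name, x$x_name, x$n, x$slope,
              x$ci95_slope[1L], x$ci95_slope[2L], x$r_squared))
  invisible(x)
}

#' Compare a fitted exponent with the isometric expectation
#'
#' Under geometric similarity, lengths scale with the 1/2 power of total
#' surface area, areas with the first power, and volume with the 3/2 power.
#' The fit is "consistent" when the expected slope lies inside its 95% CI;
#' otherwise the side is reported.
#'
#' @param fit an [allometric_fit()] with `mode = "loglog"`.
#' @param expected_slope the isometric exponent (0.5, 1, or 1.5).
#' @return `"consistent"`, `"steeper"`, or `"shallower"`.
#' @export
isometry_check <- function(fit, expected_slope) {
  if (fit$mode != "loglog") stop("isometry_check() applies to loglog fits")
  ci <- fit$ci95_slope
  # guard against zero-width CIs from numerically perfect fits
  eps <- 1e-8 * (1 + abs(expected_slope))
  if (expected_slope >= ci[1L] - eps && expected_slope <= ci[2L] + eps)
    return("consistent")
  if (fit$slope > expected_slope) "steeper" else "shallower"
}

#' Linear trend of a morphometric value with age
#'
#' Ordinary least-squares fit of `value` on `age` (years), with slope
#' p-value and 95% CI, for aging analyses such as cortical thinning.
#'
#' @param ages years.
#' @param values the measure per subject.
#' @return list with `slope`, `intercept`, `p_slope`, `ci95_slope`,
#'   `r_squared`, `n`.
#' @export
age_trend <- function(ages, values) {
  if (length(ages) != length(values)) stop("ages and values lengths differ")
  if (length(ages) < 3L) stop("age_trend() needs n >= 3")
  if (sd(ages) == 0) stop("ages are constant")
  fit <- lm(values ~ ages)
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(suppressMessages(confint(fit, "ages", level = 0.95)))
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       p_slope = sm$coefficients[2L, 4L],
       ci95_slope = as.numeric(ci),
       r_squared = sm$r.squared,
       n = length(ages))
}

#' Reciprocal of a scaling exponent at printed precision
#'
#' Inverting a power law `y ~ x^b` gives `x ~ y^(1/b)`; this helper reports
#' `1/b` rounded to the stated number of digits (e.g. 1/0.82 = 1.22,
#' 1/1.16 = 0.86 at two digits).
#'
#' @param slope the fitted exponent.
#' @param digits decimal digits to round to.
#' @return the rounded reciprocal exponent.
#' @export
reciprocal_exponent <- function(slope, digits = 2L) {
  if (slope == 0) stop("cannot invert a zero exponent")
  round(1 / slope, digits)
}
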