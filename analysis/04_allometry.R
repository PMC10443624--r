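#!/usr/bin/env Rscript
# Allometric scaling across the isometric phantom family: log-log fits of
# thickness, folding amplitude, exposed area and volume against total pial
# area, a semilog fit for GI, and the comparison of every exponent with the
# geometric-similarity reference (1/2 for lengths, 1 for areas, 3/2 for
# volume). An exponent-recovery check on a noisy synthetic cohort follows.

suppressPackageStartupMessages(library(cortimorph))
out <- "results/allometry"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

base <- make_bumpy_pair(seed = 1)
scales <- c(1, 1.5, 2, 3, 4)
family <- make_isometric_family(base, scales)
# the wrap scale is a length: select it once on the base subject and scale
# it with size, as one alpha per species
alpha0 <- select_alpha(base$pial)
subjects <- lapply(seq_along(family), function(i)
  list(pial = family[[i]]$pial, white = family[[i]]$white,
       species = sprintf("scale%g", scales[i]), subject_id = "s1",
       alpha = alpha0 * scales[i]))
res <- run_cohort(subjects, config = pipeline_config(out_dir = out))

expected <- c(thickness = 0.5, amplitude = 0.5, exposed_area = 1,
              volume = 1.5, gi = NA)
rows <- lapply(names(res$fits), function(nm) {
  f <- res$fits[[nm]]
  data.frame(quantity = nm, mode = f$mode, slope = f$slope,
             ci_lo = f$ci95_slope[1], ci_hi = f$ci95_slope[2],
             r_squared = f$r_squared,
             isometric = expected[[nm]],
             verdict = if (f$mode == "loglog" && !is.na(expected[[nm]]))
               isometry_check(f, expected[[nm]]) else NA)
})
fits <- do.call(rbind, rows)
write.csv(fits, file.path(out, "isometric_family_fits.csv"), row.names = FALSE)
cat("Isometric family (pure size change): every exponent must sit on its\n")
cat("geometric-similarity value and GI must not trend with size.\n\n")
print(fits, row.names = FALSE)
cat("\nNote: these fits are near-perfect, so their CIs are narrower than the\n")
cat("wrap discretization error; slopes within ~1% of the reference are\n")
cat("isometric for practical purposes even where the verdict differs.\n")

# exponent recovery on a cohort built with a deliberately shallow thickness
# exponent (0.2 instead of the isometric 0.5), with 5% lognormal noise
co <- make_allometric_cohort(n_species = 8,
                             exponents = list(thickness = 0.2, amplitude = 0.5),
                             noise = 0.05, seed = 2, subdivisions = 3)
fit_t <- allometric_fit(co$table$area, co$table$thickness, "loglog",
                        "total_area_mm2", "thickness_mm")
cat(sprintf("\nShallow-cohort thickness exponent: %.3f [%.3f, %.3f] -> %s vs 1/2\n",
            fit_t$slope, fit_t$ci95_slope[1], fit_t$ci95_slope[2],
            isometry_check(fit_t, 0.5)))
write.csv(data.frame(slope = fit_t$slope, ci_lo = fit_t$ci95_slope[1],
                     ci_hi = fit_t$ci95_slope[2], r_squared = fit_t$r_squared,
                     verdict = isometry_check(fit_t, 0.5)),
          file.path(out, "shallow_cohort_fit.csv"), row.names = FALSE)
cat("Tables written under", out, "\n")
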