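#!/usr/bin/env Rscript
# Aging analysis on a synthetic longitudinal cohort: subjects share one
# cortical geometry while thickness declines linearly with age (built-in
# atrophy of 0.01 mm/year); the cohort age trends must recover the thinning
# and leave the thickness ratio flat.

suppressPackageStartupMessages(library(cortimorph))
out <- "results/aging"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ages <- seq(5, 60, by = 5)
subjects <- lapply(seq_along(ages), function(i) {
  ph <- make_bumpy_pair(base_thickness = 2.2 - 0.01 * ages[i], seed = 1,
                        subdivisions = 3)
  list(pial = ph$pial, white = ph$white, species = "synthetic",
       subject_id = sprintf("age%02d", ages[i]), age = ages[i])
})
res <- run_cohort(subjects, config = pipeline_config())
write.csv(res$cohort, file.path(out, "aging_cohort.csv"), row.names = FALSE)

tr <- res$age_trends
tab <- data.frame(
  measure = c("mean_thickness_mm", "thickness_ratio", "folding_amplitude_mm"),
  slope_per_year = c(tr$thickness$slope, tr$thickness_ratio$slope, tr$depth$slope),
  p = c(tr$thickness$p_slope, tr$thickness_ratio$p_slope, tr$depth$p_slope))
write.csv(tab, file.path(out, "age_trends.csv"), row.names = FALSE)

cat("Age trends over the synthetic cohort (built-in thinning 0.01 mm/yr):\n")
print(tab, row.names = FALSE)
cat("\nThickness declines at the built-in rate while the convex/concave\n")
cat("ratio stays flat: gyri and sulci thin proportionately.\n")
cat("Tables written under", out, "\n")
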