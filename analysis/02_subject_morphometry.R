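#!/usr/bin/env Rscript
# Runs the per-subject morphometry pipeline (curvature, shape index,
# thickness, alpha surface, sulcal depth, global metrics) on the smooth
# control and the default folded phantom; writes per-vertex maps and the
# subject summaries under results/subjects/.

suppressPackageStartupMessages(library(cortimorph))
out <- "results/subjects"

sphere <- make_sphere_pair(R = 10, thickness = 2, subdivisions = 3)
folded <- make_bumpy_pair(seed = 1)

cfg <- pipeline_config(out_dir = out, verbose = TRUE)
rec_sphere <- run_subject(sphere$pial, sphere$white,
                          species = "smooth", subject_id = "s1", config = cfg)
rec_folded <- run_subject(folded$pial, folded$white,
                          species = "folded", subject_id = "f1", config = cfg)

tab <- rbind(as.data.frame(rec_sphere), as.data.frame(rec_folded))
write.csv(tab, file.path(out, "subject_summaries.csv"), row.names = FALSE)
cat("\nSubject summaries (also in results/subjects/subject_summaries.csv):\n")
print(tab[, c("species", "gi", "mean_thickness_mm", "folding_amplitude_mm",
              "thickness_ratio")], row.names = FALSE)
cat("\nThe smooth control sits at GI ~ 1 with a unit thickness ratio and no\n")
cat("sulcal depth; the folded phantom is gyrencephalic (GI > 1) with thick\n")
cat("convex crowns and thin concave fundi (ratio > 1).\n")
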