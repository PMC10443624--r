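#!/usr/bin/env Rscript
# Shape-resolved thickness analysis on the folded phantom: 9-way and 3-way
# class statistics, kernel density profiles of thickness per major shape,
# Welch/Cohen contrasts between classes, and the zero-coupling control.

suppressPackageStartupMessages(library(cortimorph))
out <- "results/shape_thickness"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

process <- function(ph) {
  si <- smooth_vertex_field(ph$pial, shape_index(principal_curvatures(ph$pial)), 2)
  labels <- classify_shapes(vertex_field(pmin(1, pmax(-1, as.numeric(si))), ph$pial))
  th <- smooth_vertex_field(ph$pial, cortical_thickness(ph$pial, ph$white), 2,
                            exclude_zero = TRUE)
  list(labels = labels, thickness = th, si = si)
}

folded <- process(make_bumpy_pair(seed = 1))
tab <- shape_binned_stats(folded$thickness, folded$labels)
write.csv(tab, file.path(out, "shape_binned_thickness.csv"), row.names = FALSE)

# kernel density profiles per major shape
t <- as.numeric(folded$thickness)
grid <- seq(1, 2.2, length.out = 200)
kde <- do.call(rbind, lapply(levels(folded$labels$major), function(cl) {
  cbind(class = cl, kde_profile(t[folded$labels$major == cl & t > 0], grid))
}))
write.csv(kde, file.path(out, "thickness_kde_profiles.csv"), row.names = FALSE)

pools <- split(t[t > 0], folded$labels$major[t > 0])
contrasts <- list(
  convex_saddle = shape_contrast(pools$convex, pools$saddle, "convex", "saddle"),
  concave_saddle = shape_contrast(pools$concave, pools$saddle, "concave", "saddle"),
  convex_concave = shape_contrast(pools$convex, pools$concave, "convex", "concave"))
ct <- do.call(rbind, lapply(contrasts, function(x)
  data.frame(a = x$class_a, b = x$class_b, mean_a = x$mean_a, mean_b = x$mean_b,
             t = x$t, p = x$p, d = x$d)))
write.csv(ct, file.path(out, "shape_contrasts.csv"), row.names = FALSE)

# local correlations of thickness with shape and depth
pial <- make_bumpy_pair(seed = 1)$pial
w <- build_alpha_surface(pial, alpha = "auto")
dep <- sulcal_depth(pial, w)
corr <- data.frame(
  pair = c("thickness_vs_SI", "thickness_vs_depth"),
  r = c(local_correlation(folded$thickness, folded$si)$r,
        local_correlation(folded$thickness, dep)$r))
write.csv(corr, file.path(out, "local_correlations.csv"), row.names = FALSE)

# zero-coupling control: the ratio collapses to 1
ctrl <- process(make_bumpy_pair(coupling = 0, seed = 1))
ratio0 <- thickness_ratio(ctrl$thickness, ctrl$labels)

maj <- tab[tab$scheme == "major", ]
cat("Major-class thickness means (mm):\n")
print(maj, row.names = FALSE)
cat(sprintf("\nConvex-vs-concave contrast: d = %.2f, p = %.3g\n",
            contrasts$convex_concave$d, contrasts$convex_concave$p))
cat(sprintf("Thickness correlates with shape (r = %.2f vs SI) and depth (r = %.2f).\n",
            corr$r[1], corr$r[2]))
cat(sprintf("Zero-coupling control ratio: %.3f (vs %.3f with coupling).\n",
            ratio0, maj$mean[maj$class == "convex"] / maj$mean[maj$class == "concave"]))
cat("Tables written under", out, "\n")
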