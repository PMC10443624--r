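#' Gyrification index
#'
#' Ratio of total (pial) to exposed (alpha) surface area; 1 for a smooth
#' convex brain, > 1 with folding.
#'
#' @param total_area total pial area, mm^2.
#' @param exposed_area alpha-surface area, mm^2.
#' @return dimensionless GI.
#' @export
gyrification_index <- function(total_area, exposed_area) {
  if (total_area <= 0 || exposed_area <= 0) stop("areas must be positive")
  if (exposed_area > total_area * 1.02)
    warning("exposed area exceeds total area by ",
            round(100 * (exposed_area / total_area - 1), 1),
            "%: the alpha wrap may have failed")
  total_area / exposed_area
}

#' Folding amplitude (average sulcal depth)
#'
#' Vertex-level mean of the sulcal depth field over all pial vertices.
#' @param depth a non-negative depth [vertex_field()] (mm).
#' @return mm.
#' @export
folding_amplitude <- function(depth) {
  d <- as.numeric(depth)
  if (any(d < -1e-9)) stop("depth field must be non-negative")
  mean(d)
}

#' Convex/concave cortical thickness ratio
#'
#' Mean thickness over convex-labelled vertices divided by the mean over
#' concave-labelled vertices, excluding floored zeros.
#'
#' @param thickness thickness [vertex_field()] (mm).
#' @param labels a `shape_labels` object aligned to the same mesh.
#' @return dimensionless ratio.
#' @export
thickness_ratio <- function(thickness, labels) {
  t <- as.numeric(thickness)
  if (length(t) != length(labels$major))
    stop("thickness and labels are not aligned (", length(t), " vs ",
         length(labels$major), ")")
  cx <- t[labels$major == "convex" & t > 0]
  cc <- t[labels$major == "concave" & t > 0]
  if (length(cx) == 0L) stop("no non-zero convex vertices")
  if (length(cc) == 0L) stop("no non-zero concave vertices")
  mean(cx) / mean(cc)
}

# Subject-level ratio with the lissencephalic limit: on a smooth convex
# cortex one of the classes is (near-)empty and the convex/concave
# distinction is vacuous, so a missing class falls back to the overall mean
# and a perfectly smooth subject reports a ratio of 1.
thickness_ratio_lenient <- function(thickness, labels) {
  t <- as.numeric(thickness)
  overall <- t[t > 0]
  cx <- t[labels$major == "convex" & t > 0]
  cc <- t[labels$major == "concave" & t > 0]
  if (length(cx) == 0L) cx <- overall
  if (length(cc) == 0L) cc <- overall
  mean(cx) / mean(cc)
}

#' Reduce a processed subject to its global morphometry record
#'
#' Pools the supplied per-vertex fields (one whole cortex, or two hemispheres
#' concatenated beforehand with [combine_meshes()]) into the subject-level
#' metrics: total and exposed areas, GI, enclosed volume, vertex-level mean
#' thickness (non-zero vertices), folding amplitude, thickness ratio, and
#' per-shape thickness/depth tables. If a major shape class is empty (a
#' perfectly smooth cortex has no concave vertices) the thickness ratio uses
#' the overall mean for the missing class, giving the lissencephalic limit
#' of 1; the strict [thickness_ratio()] by contrast raises an error.
#'
#' @param pial,white closed meshes of the cortex.
#' @param wrap `alpha_surface` for the pial surface.
#' @param thickness,depth [vertex_field()]s on the pial mesh.
#' @param labels `shape_labels` on the pial mesh.
#' @param species,subject_id labels.
#' @param age years (optional).
#' @param partial flag a record whose inputs were incomplete.
#' @return object of class `subject_morphometry`.
#' @export
summarize_subject <- function(pial, white, wrap, thickness, depth, labels,
                              species = "phantom", subject_id = "s1",
                              age = NA_real_, partial = FALSE) {
  check_alignment(thickness, pial)
  check_alignment(depth, pial)
  t <- as.numeric(thickness)
  total_area <- surface_area(pial)
  exposed_area <- surface_area(wrap$mesh)
  res <- structure(list(
    species = species, subject_id = subject_id, age = age,
    total_area = total_area,
    exposed_area = exposed_area,
    gi = gyrification_index(total_area, exposed_area),
    volume = enclosed_volume(pial),
    mean_thickness = mean(t[t > 0]),
    folding_amplitude = folding_amplitude(depth),
    thickness_ratio = thickness_ratio_lenient(thickness, labels),
    per_shape_thickness = shape_binned_stats(thickness, labels),
    per_shape_depth = shape_binned_stats(depth, labels, exclude_zeros = FALSE),
    n_vertices = n_vertices(pial),
    partial = partial), class = "subject_morphometry")
  res
}

#' @export
print.subject_morphometry <- function(x, ...) {
  cat("subject_morphometry:", x$species, "/", x$subject_id, "\n")
  print(as.data.frame(x))
  invisible(x)
}

#' Flatten a subject record to one data.frame row
#'
#' Column names carry units (e.g. `total_area_mm2`).
#' @param x a `subject_morphometry`.
#' @param ... unused.
#' @return one-row data.frame.
#' @export
as.data.frame.subject_morphometry <- function(x, ...) {
  data.frame(species = x$species, subject_id = x$subject_id, age = x$age,
             total_area_mm2 = x$total_area, exposed_area_mm2 = x$exposed_area,
             gi = x$gi, volume_mm3 = x$volume,
             mean_thickness_mm = x$mean_thickness,
             folding_amplitude_mm = x$folding_amplitude,
             thickness_ratio = x$thickness_ratio,
             n_vertices = x$n_vertices, partial = x$partial)
}
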