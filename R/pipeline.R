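#' Pipeline configuration
#'
#' One configuration fully determines all outputs of [run_subject()] and
#' [run_cohort()].
#'
#' @param conditioning a [conditioning_config()].
#' @param thickness a [thickness_config()].
#' @param alpha wrap scale in mm, or `"auto"` for [select_alpha()].
#' @param orientation shape-index orientation (`"paper"`: convex negative).
#' @param out_dir directory for per-vertex and summary outputs; `NULL`
#'   disables writing.
#' @param surface_format format for written surfaces.
#' @param seed recorded seed (the pipeline itself is deterministic; the seed
#'   governs phantom generation).
#' @param verbose log each stage with parameters and wall time.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(conditioning = conditioning_config(
                              laplacian_iters = 0L, taubin_iters = 10L),
                            thickness = thickness_config(),
                            alpha = "auto",
                            orientation = c("paper", "koenderink"),
                            out_dir = NULL,
                            surface_format = "ply",
                            seed = 1L,
                            verbose = FALSE) {
  orientation <- match.arg(orientation)
  structure(list(conditioning = conditioning, thickness = thickness,
                 alpha = alpha, orientation = orientation, out_dir = out_dir,
                 surface_format = surface_format, seed = as.integer(seed),
                 verbose = verbose),
            class = "pipeline_config")
}

#' Species size-class target densities
#'
#' Default sampling spacings by cortex size: ~2 mm for x-large, ~1.5 mm for
#' large, ~1 mm for medium and ~0.5 mm for small cortices, keyed on total
#' pial area. Boundaries are configurable because size groups come from
#' natural breaks in the area distribution.
#'
#' @param total_area total pial area, mm^2.
#' @param breaks area thresholds (mm^2) separating small/medium/large/x-large.
#' @param densities target densities (mm) for the four classes, small first.
#' @return target density in mm.
#' @export
size_class_density <- function(total_area,
                               breaks = c(4000, 20000, 60000),
                               densities = c(0.5, 1, 1.5, 2)) {
  densities[findInterval(total_area, breaks) + 1L]
}

#' Process one subject through the full morphometry pipeline
#'
#' Stages: mesh conditioning (optional resampling to the target density,
#' Taubin then Laplacian smoothing of both surfaces), per-vertex curvature
#' and shape index on the pial surface, shape classification, bidirectional
#' cortical thickness with the floor rule, alpha surface and sulcal depth,
#' measure smoothing (two iterations of weighted averaging, floored zeros
#' excluded), and reduction to the subject morphometry record. Deterministic
#' given its inputs and configuration.
#'
#' @param pial,white closed meshes (or file paths readable by
#'   [read_surface()]).
#' @param species,subject_id labels for the record.
#' @param age years (optional).
#' @param config a [pipeline_config()].
#' @return a `subject_morphometry` (see [summarize_subject()]), with the
#'   `alpha_surface` attached as attribute `wrap`.
#' @export
run_subject <- function(pial, white, species = "phantom", subject_id = "s1",
                        age = NA_real_, config = pipeline_config()) {
  t_all <- proc.time()[3L]
  log_stage <- function(stage, ...) {
    if (config$verbose)
      message(sprintf("[%s/%s] %s %s (%.1fs)", species, subject_id, stage,
                      paste0(...), proc.time()[3L] - t_all))
  }
  fail <- function(stage, msg, hint) {
    stop("stage '", stage, "' failed for subject ", species, "/", subject_id,
         ": ", msg, " (", hint, ")", call. = FALSE)
  }
  if (is.character(pial)) {
    if (!file.exists(pial)) fail("read", paste0("missing pial surface: ", pial),
                                 "check the configured path")
    pial <- read_surface(pial)
  }
  if (is.character(white)) {
    if (!file.exists(white)) fail("read", paste0("missing white surface: ", white),
                                  "check the configured path")
    white <- read_surface(white)
  }
  cc <- config$conditioning
  if (!is.null(cc$target_density)) {
    target_faces <- round(2 * surface_area(pial) / cc$target_density^2)
    pial <- remesh_to_target(pial, target_faces)
    white <- remesh_to_target(white, round(2 * surface_area(white) / cc$target_density^2))
    log_stage("remesh", sprintf("target density %.3g mm -> %d faces",
                                cc$target_density, n_faces(pial)))
  }
  if (cc$taubin_iters > 0L) {
    pial <- taubin_smooth(pial, cc$taubin_iters, cc$taubin_shrink, cc$taubin_inflate)
    white <- taubin_smooth(white, cc$taubin_iters, cc$taubin_shrink, cc$taubin_inflate)
    log_stage("taubin", sprintf("%d iters (lambda %.2f, mu %.2f)",
                                cc$taubin_iters, cc$taubin_shrink, cc$taubin_inflate))
  }
  if (cc$laplacian_iters > 0L) {
    pial <- laplacian_smooth(pial, cc$laplacian_iters, cc$laplacian_factor)
    white <- laplacian_smooth(white, cc$laplacian_iters, cc$laplacian_factor)
    log_stage("laplacian", sprintf("%d iters (factor %.2f)",
                                   cc$laplacian_iters, cc$laplacian_factor))
  }
  bundle <- principal_curvatures(pial)
  log_stage("curvature", "quadric fit")
  si_raw <- shape_index(bundle, orientation = config$orientation)
  si <- smooth_vertex_field(pial, si_raw, iterations = cc$field_smooth_iters,
                            weights = cc$field_smooth_weights)
  si <- vertex_field(pmin(1, pmax(-1, as.numeric(si))), pial)
  attr(si, "flat") <- attr(si_raw, "flat")
  attr(si, "orientation") <- config$orientation
  labels <- classify_shapes(si)
  log_stage("shape", sprintf("%d convex / %d saddle / %d concave",
                             sum(labels$major == "convex"),
                             sum(labels$major == "saddle"),
                             sum(labels$major == "concave")))
  th_raw <- cortical_thickness(pial, white, config$thickness)
  th <- smooth_vertex_field(pial, th_raw, iterations = cc$field_smooth_iters,
                            weights = cc$field_smooth_weights,
                            exclude_zero = config$thickness$exclude_zeros)
  log_stage("thickness", sprintf("mean %.3g mm", mean(as.numeric(th)[as.numeric(th) > 0])))
  wrap <- build_alpha_surface(pial, alpha = config$alpha)
  log_stage("alpha", sprintf("alpha %.3g mm%s", wrap$alpha,
                             if (wrap$auto_selected) " (auto)" else ""))
  depth <- sulcal_depth(pial, wrap, smooth_iters = cc$field_smooth_iters)
  log_stage("depth", sprintf("mean %.3g mm", mean(as.numeric(depth))))
  record <- summarize_subject(pial, white, wrap, th, depth, labels,
                              species = species, subject_id = subject_id, age = age)
  if (!is.null(config$out_dir)) {
    dir <- file.path(config$out_dir, paste0(species, "_", subject_id))
    ok <- FALSE
    on.exit(if (!ok) unlink(dir, recursive = TRUE), add = TRUE)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    maps <- data.frame(vertex = seq_len(n_vertices(pial)) - 1L,
                       k1 = bundle$k1, k2 = bundle$k2, K = bundle$K, H = bundle$H,
                       SI = as.numeric(si),
                       minor = shape_codes(labels)$minor,
                       major = shape_codes(labels)$major,
                       thickness = as.numeric(th), depth = as.numeric(depth))
    write.csv(maps, file.path(dir, "vertex_maps.csv"), row.names = FALSE, quote = FALSE)
    write_surface(wrap$mesh, file.path(dir, paste0("alpha.", config$surface_format)),
                  format = config$surface_format)
    write.csv(as.data.frame(record), file.path(dir, "summary.csv"),
              row.names = FALSE, quote = FALSE)
    ok <- TRUE
    log_stage("write", dir)
  }
  attr(record, "wrap") <- wrap
  attr(record, "fields") <- list(thickness = th, depth = depth, si = si,
                                 labels = labels)
  record
}

#' Process a cohort and aggregate cohort statistics
#'
#' Runs every subject through [run_subject()], collects one morphometry row
#' per subject, species mean +/- sd summaries, cross-species allometric fits
#' against total pial area (log-log for thickness, folding amplitude,
#' exposed area and volume; semilog for GI; one point per species, using
#' species means when N > 1), pooled-vertex shape contrasts, and age trends
#' when ages are available. Individual subject failures are recorded, not
#' fatal.
#'
#' @param subjects list; each element either a `phantom_pair` or a list with
#'   `pial`, `white` (meshes or paths) and optional `species`, `subject_id`,
#'   `age`, and `alpha` (a per-subject wrap scale overriding the
#'   configuration, e.g. one chosen per species and scaled with size).
#' @param config a [pipeline_config()].
#' @return object of class `cohort_result`: list with `cohort` (data.frame),
#'   `species_summary`, `fits` (list of [allometric_fit()]), `contrasts`,
#'   `age_trends`, `failures`, `records`.
#' @export
run_cohort <- function(subjects, config = pipeline_config()) {
  records <- list()
  failures <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    if (inherits(s, "phantom_pair"))
      s <- list(pial = s$pial, white = s$white)
    species <- s$species %||% "phantom"
    sid <- s$subject_id %||% sprintf("s%02d", i)
    cfg_i <- config
    if (!is.null(s$alpha)) cfg_i$alpha <- s$alpha
    rec <- tryCatch(
      run_subject(s$pial, s$white, species = species, subject_id = sid,
                  age = s$age %||% NA_real_, config = cfg_i),
      error = function(e) e)
    if (inherits(rec, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(species = species, subject_id = sid,
                   error = conditionMessage(rec))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  if (length(records) == 0L)
    stop("all subjects failed:\n",
         paste(vapply(failures, function(f) paste0("  ", f$species, "/",
                                                   f$subject_id, ": ", f$error),
                      character(1)), collapse = "\n"))
  cohort <- do.call(rbind, lapply(records, as.data.frame))
  num_cols <- c("total_area_mm2", "exposed_area_mm2", "gi", "volume_mm3",
                "mean_thickness_mm", "folding_amplitude_mm", "thickness_ratio")
  sp_mean <- stats::aggregate(cohort[num_cols], by = list(species = cohort$species), mean)
  sp_sd <- stats::aggregate(cohort[num_cols], by = list(species = cohort$species), sd)
  names(sp_sd)[-1L] <- paste0(names(sp_sd)[-1L], "_sd")
  sp_n <- stats::aggregate(list(n = cohort$species), by = list(species = cohort$species), length)
  species_summary <- merge(merge(sp_mean, sp_sd, by = "species"), sp_n, by = "species")
  fits <- NULL
  if (nrow(sp_mean) >= 3L) {
    fits <- list(
      thickness = allometric_fit(sp_mean$total_area_mm2, sp_mean$mean_thickness_mm,
                                 "loglog", "total_area_mm2", "mean_thickness_mm"),
      amplitude = tryCatch(
        allometric_fit(sp_mean$total_area_mm2, sp_mean$folding_amplitude_mm,
                       "loglog", "total_area_mm2", "folding_amplitude_mm"),
        error = function(e) NULL),
      exposed_area = allometric_fit(sp_mean$total_area_mm2, sp_mean$exposed_area_mm2,
                                    "loglog", "total_area_mm2", "exposed_area_mm2"),
      volume = allometric_fit(sp_mean$total_area_mm2, sp_mean$volume_mm3,
                              "loglog", "total_area_mm2", "volume_mm3"),
      gi = allometric_fit(sp_mean$total_area_mm2, sp_mean$gi,
                          "semilog", "total_area_mm2", "gi"))
  }
  # pooled-vertex thickness contrasts between major shapes
  pools <- list(convex = numeric(0), saddle = numeric(0), concave = numeric(0))
  for (rec in records) {
    fl <- attr(rec, "fields")
    t <- as.numeric(fl$thickness)
    for (cl in names(pools))
      pools[[cl]] <- c(pools[[cl]], t[fl$labels$major == cl & t > 0])
  }
  contrasts <- NULL
  if (all(vapply(pools, length, integer(1)) >= 2L)) {
    contrasts <- list(
      convex_saddle = shape_contrast(pools$convex, pools$saddle, "convex", "saddle"),
      concave_saddle = shape_contrast(pools$concave, pools$saddle, "concave", "saddle"),
      convex_concave = shape_contrast(pools$convex, pools$concave, "convex", "concave"))
  }
  age_trends <- NULL
  ages <- cohort$age
  if (sum(is.finite(ages)) >= 3L && sd(ages[is.finite(ages)]) > 0) {
    ok <- is.finite(ages)
    age_trends <- list(
      thickness = age_trend(ages[ok], cohort$mean_thickness_mm[ok]),
      thickness_ratio = age_trend(ages[ok], cohort$thickness_ratio[ok]),
      depth = age_trend(ages[ok], cohort$folding_amplitude_mm[ok]))
  }
  res <- structure(list(cohort = cohort, species_summary = species_summary,
                        fits = fits, contrasts = contrasts,
                        age_trends = age_trends,
                        failures = if (length(failures)) do.call(rbind, failures) else NULL,
                        records = records),
                   class = "cohort_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(cohort, file.path(config$out_dir, "cohort.csv"),
              row.names = FALSE, quote = FALSE)
    if (!is.null(fits)) {
      ft <- do.call(rbind, lapply(fits, function(f)
        data.frame(y = f$y_name, x = f$x_name, mode = f$mode, slope = f$slope,
                   ci_lo = f$ci95_slope[1L], ci_hi = f$ci95_slope[2L],
                   r_squared = f$r_squared, p = f$p_slope, n = f$n)))
      write.csv(ft, file.path(config$out_dir, "allometric_fits.csv"),
                row.names = FALSE, quote = FALSE)
    }
  }
  res
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("cohort_result:", nrow(x$cohort), "subjects,",
      length(unique(x$cohort$species)), "species\n")
  if (!is.null(x$fits)) for (f in x$fits) print(f)
  invisible(x)
}
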