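#' Pipeline run configuration
#'
#' Bundles the stage configurations, the global seed and the few scalar
#' choices (atlas binarisation threshold, hull dilation radius, cochlear
#' grading detection floor, crop centre) used by [run_subject()] /
#' [run_cohort()].
#'
#' @param preprocess a [preprocess_config()].
#' @param registration a [registration_config()].
#' @param volt a [volt_config()].
#' @param atlas_threshold occupancy threshold binarising the registered
#'   atlas.
#' @param hull_dilate_voxels dilation radius applied to the hull before
#'   fusion.
#' @param detection_floor cochlear grading detection floor (fraction of the
#'   cochlear slice fluid area).
#' @param crop_center_mm crop centre, mm offsets from the grid centre.
#' @param seed global seed for the stochastic stages.
#' @return a `run_config` list.
#' @export
run_config <- function(preprocess = preprocess_config(),
                       registration = registration_config(),
                       volt = volt_config(),
                       atlas_threshold = 0.5,
                       hull_dilate_voxels = 1L,
                       detection_floor = 0.05,
                       crop_center_mm = c(0, 0, 0),
                       seed = 1L) {
  registration$seed <- as.integer(seed)
  structure(list(preprocess = preprocess, registration = registration,
                 volt = volt, atlas_threshold = atlas_threshold,
                 hull_dilate_voxels = as.integer(hull_dilate_voxels),
                 detection_floor = detection_floor,
                 crop_center_mm = crop_center_mm, seed = as.integer(seed)),
            class = "run_config")
}

#' Dice overlap coefficient of two binary masks
#'
#' @param a,b logical arrays (or logical `volume`s) of identical shape.
#' @return `2|A n B| / (|A| + |B|)`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  if (is_volume(a)) a <- a$data
  if (is_volume(b)) b <- b$data
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# crop + upsample the phantom ground truth onto the analysis grid
# (nearest-neighbour, so labels stay labels)
truth_on_analysis_grid <- function(truth, cfg) {
  up <- function(v) upsample_labels(crop_cuboid(v, cfg$crop_center_mm, cfg$preprocess),
                                    cfg$preprocess$rescale_factor)
  list(label = up(truth$label), compartment = up(truth$compartment),
       side = up(truth$side))
}

run_provenance <- function(cfg) {
  list(config_hash = rlang::hash(cfg),
       package_version = as.character(utils::packageVersion("hydroquant")),
       timestamp = format(Sys.time(), tz = "UTC"))
}

#' Run the full quantification pipeline on one subject
#'
#' Executes, in order: preprocessing (HYDROPS, Mi2, crop, 8-bit, rescale,
#' MRC denoise), atlas registration, hull extraction, hull dilation and
#' fusion, the VOLT ensemble, compartment splitting, volumetric measures
#' and hydrops grading. Any stage failure is caught and returned as a
#' partial result naming the failing stage.
#'
#' @param triplet list of `volume`s `mrc`, `ppi`, `pei`.
#' @param atlas a `probabilistic_atlas` (e.g. from [build_atlas()]).
#' @param cfg a [run_config()].
#' @param compartment_regions integer array (1 cochlea, 2 vestibule) on the
#'   analysis grid, or crop boxes for [split_compartments()]; may be
#'   omitted when `truth` is given.
#' @param truth optional `labyrinth_mask` ground truth (phantom subjects):
#'   supplies the compartment regions and enables truth-vs-measured
#'   comparisons.
#' @param leading_side `"left"` or `"right"` for the ipsi/contra pairing.
#' @param out_dir optional directory; when given, all intermediates
#'   (hull, votes, ELS mask) and result tables are written there.
#' @return a `subject_result`: measures, paired measures, grades, hull and
#'   ELS objects, the registration parameters, provenance, and `error`
#'   (`NULL` on success, otherwise the failing stage).
#' @export
run_subject <- function(triplet, atlas, cfg = run_config(),
                        compartment_regions = NULL, truth = NULL,
                        leading_side = "right", out_dir = NULL) {
  res <- structure(list(error = NULL, failed_stage = NULL,
                        provenance = run_provenance(cfg)),
                   class = "subject_result")
  stage <- function(name, expr) {
    if (!is.null(res$error)) return(NULL)
    out <- tryCatch(expr, error = function(e) {
      res$error <<- conditionMessage(e)
      res$failed_stage <<- name
      NULL
    })
    out
  }
  pre <- stage("preprocess", preprocess_subject(triplet, cfg$preprocess,
                                                cfg$crop_center_mm))
  reg <- stage("register", register_affine(atlas, pre$mrc, cfg$registration))
  roi <- stage("atlas_roi", atlas_roi(atlas, pre$mrc, reg, cfg$atlas_threshold))
  hull <- stage("hull", extract_hull(pre$mrc, roi))
  dhull <- stage("dilate", dilate_hull(hull, cfg$hull_dilate_voxels))
  fused <- stage("fuse", fuse(dhull, pre$mi2))
  volt <- stage("volt", run_volt(fused, hull, cfg$volt))
  if (is.null(compartment_regions) && !is.null(truth)) {
    compartment_regions <- stage("compartments",
                                 truth_on_analysis_grid(truth, cfg)$compartment$data)
  }
  els <- stage("split", split_compartments(volt$els, compartment_regions))
  comp_arr <- if (is.array(compartment_regions)) compartment_regions else
    stage("split", {
      tmp <- split_compartments(structure(list(
        mask = as_volume(array(TRUE, dim(hull$mask$data)), hull$mask$voxel_mm),
        cochlea = NULL, vestibule = NULL), class = "els_mask"), compartment_regions)
      (tmp$cochlea$data * 1L) + (tmp$vestibule$data * 2L)
    })
  measures <- stage("measure", els_measures(els, hull, comp_arr))
  pairs <- stage("measure", {
    p <- pair_measures(measures, leading_side)
    class(p) <- c("els_measures", class(p))
    p
  })
  grades <- stage("grade", grade_subject(els, hull, comp_arr, cfg$detection_floor,
                                         slab_voxels = cfg$preprocess$rescale_factor))

  res$registration <- reg
  res$hull <- hull
  res$els <- els
  res$votes <- if (!is.null(volt)) volt$aggregation else NULL
  res$measures <- measures
  res$pairs <- pairs
  res$grades <- grades
  if (!is.null(truth)) res$truth_analysis <- truth_on_analysis_grid(truth, cfg)

  if (!is.null(out_dir) && is.null(res$error)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_volume(as_volume(res$votes$votes, hull$mask$voxel_mm),
                 file.path(out_dir, "votes.nii.gz"))
    write_volume(as_volume(hull$mask$data * 1, hull$mask$voxel_mm),
                 file.path(out_dir, "hull.nii.gz"))
    write_volume(as_volume(els$mask$data * 1, els$mask$voxel_mm),
                 file.path(out_dir, "els_mask.nii.gz"))
    utils::write.csv(measures, file.path(out_dir, "measures.csv"), row.names = FALSE)
    utils::write.csv(grades, file.path(out_dir, "grades.csv"), row.names = FALSE)
    jsonlite::write_json(res$provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  res
}

#' @export
print.subject_result <- function(x, ...) {
  if (!is.null(x$error)) {
    cat(sprintf("<subject_result> FAILED at stage '%s': %s\n",
                x$failed_stage, x$error))
  } else {
    cat("<subject_result>\n")
    print(x$grades)
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.subject_result <- function(x, ...) x$measures

#' @exportS3Method generics::glance
glance.subject_result <- function(x, ...) {
  ear <- dplyr::filter(x$pairs, .data$scope == "ear")
  g <- x$grades
  tibble::tibble(
    els_mean_mm3 = ear$els_mean_mm3, tfs_mean_mm3 = ear$tfs_mean_mm3,
    diff_mm3 = ear$diff_mm3, ai_pct = ear$ai_pct,
    cochlear_grade_left = g$cochlear_grade[g$side == "left"],
    cochlear_grade_right = g$cochlear_grade[g$side == "right"],
    vestibular_grade_left = g$vestibular_grade[g$side == "left"],
    vestibular_grade_right = g$vestibular_grade[g$side == "right"],
    failed_stage = x$failed_stage %||% NA_character_
  )
}

#' Run the pipeline over a synthetic cohort and compute group statistics
#'
#' Generates (or accepts) phantom images per cohort row, runs
#' [run_subject()] on each, and computes the group association statistics
#' on the results: hydrops presence by diagnosis group (chi-square with
#' phi), one-way ANOVA with Bonferroni-corrected pairwise tests on the
#' ipsilateral ELS/TFS ratio, and Spearman correlations between measured
#' ELS ratios and the neurotology record. Results are sorted by subject
#' id, so processing order never changes the report.
#'
#' @param cohort tibble from [generate_cohort()].
#' @param base_spec shared [phantom_spec()].
#' @param cfg a [run_config()].
#' @param atlas optional prebuilt `probabilistic_atlas`; built from the
#'   default-spec phantom when omitted.
#' @param seed cohort master seed (used for per-subject image seeds).
#' @return list with `subjects` (one-row-per-subject tibble), `stats`
#'   (named list of test results) and `provenance`.
#' @export
run_cohort <- function(cohort, base_spec = phantom_spec(), cfg = run_config(),
                       atlas = NULL, seed = 1L) {
  if (nrow(cohort) < 1L) stop("cohort must contain at least one subject")
  if (is.null(atlas)) {
    atlas <- build_atlas(list(build_labyrinth(base_spec)))
  }
  per_subject <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    sp <- subject_phantom_spec(row, base_spec, seed)
    subj <- make_phantom_subject(sp)
    r <- run_subject(subj$triplet, atlas, cfg, truth = subj$truth,
                     leading_side = row$leading_side)
    dplyr::bind_cols(tibble::tibble(id = row$id, group = row$group), glance(r))
  })
  per_subject <- dplyr::arrange(per_subject, .data$id)
  eh_present <- with(per_subject, cochlear_grade_left > 0 | cochlear_grade_right > 0 |
                       vestibular_grade_left > 0 | vestibular_grade_right > 0)
  stats_out <- list()
  if (length(unique(per_subject$group)) >= 2L) {
    tab <- table(per_subject$group, factor(eh_present, levels = c(TRUE, FALSE),
                                           labels = c("present", "absent")))
    stats_out$eh_presence_chi2 <- tryCatch(
      chi_square(contingency_table(unclass(as.matrix(tab)),
                                   rownames(tab), colnames(tab))),
      error = function(e) paste("not computed:", conditionMessage(e))
    )
    stats_out$els_anova <- tryCatch(
      anova_bonferroni(per_subject$els_mean_mm3, per_subject$group),
      error = function(e) paste("not computed:", conditionMessage(e))
    )
  } else {
    stats_out$note <- "group statistics not computed (n < 2 groups)"
  }
  merged <- dplyr::left_join(per_subject,
                             dplyr::select(cohort, "id", "frac_ear_ipsi",
                                           "pta_right", "pta_left"),
                             by = "id")
  if (nrow(merged) >= 3L) {
    stats_out$spearman_els_vs_truth <- spearman_assoc(
      merged$els_mean_mm3, merged$frac_ear_ipsi
    )
  }
  list(subjects = per_subject, stats = stats_out,
       provenance = run_provenance(cfg))
}
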