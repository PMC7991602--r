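#' Effect model linking ground-truth hydrops to neurotology
#'
#' Defines, per diagnosis group, the distribution of per-side endolymph
#' fractions and the monotone links from the ipsilateral whole-ear ELS
#' fraction to the neurotologic measures: pure-tone average rises with the
#' fraction, caloric slow-phase velocity and vHIT gain fall with it, VEMP
#' amplitudes fall with the vestibular fraction. `noise_scale` multiplies
#' every measurement-noise standard deviation; at 0 the links are
#' deterministic and strictly monotone, so rank correlations with the
#' ground truth are exactly +/-1.
#'
#' MD-like subjects get high ipsilateral fractions (hydropic leading ear),
#' VM-like subjects low symmetric fractions and normal neurotology,
#' VM-MD intermediate.
#'
#' @param fractions per-group list of `c(ipsi_mean, ipsi_sd, contra_mean,
#'   contra_sd)` for the endolymph fraction draws (clamped to
#'   `[0.01, 0.75]`).
#' @param pta `c(base, slope, sd)`: `PTA = base + slope * fraction` dB.
#' @param caloric `c(base, slope, sd, warm_share)`: per-side summed SPV
#'   `base * (1 - slope * fraction)` deg/s, split between the 44 degC warm
#'   (share) and 30 degC cold irrigation.
#' @param cvemp,ovemp `c(base, slope, sd)`: amplitude
#'   `base - slope * vestibular fraction` microvolts.
#' @param vhit `c(base, slope, sd)`: gain `base - slope * vestibular
#'   fraction`.
#' @param latencies means/sds of the recorded (classification-neutral)
#'   VEMP latencies, ms.
#' @param noise_scale global multiplier on the measurement noise.
#' @return an `effect_model` list.
#' @export
effect_model <- function(fractions = list(
                           VM = c(ipsi_mean = 0.025, ipsi_sd = 0.012,
                                  contra_mean = 0.025, contra_sd = 0.012),
                           MD = c(ipsi_mean = 0.45, ipsi_sd = 0.10,
                                  contra_mean = 0.08, contra_sd = 0.03),
                           `VM-MD` = c(ipsi_mean = 0.25, ipsi_sd = 0.10,
                                       contra_mean = 0.10, contra_sd = 0.04)),
                         pta = c(base = 10, slope = 80, sd = 4),
                         caloric = c(base = 28, slope = 0.85, sd = 2,
                                     warm_share = 0.52),
                         cvemp = c(base = 12, slope = 6, sd = 1.5),
                         ovemp = c(base = 10, slope = 5, sd = 1.5),
                         vhit = c(base = 0.96, slope = 0.12, sd = 0.02),
                         latencies = c(cvemp_p13_mean = 13.8, cvemp_p13_sd = 0.6,
                                       ovemp_n10_mean = 10.9, ovemp_n10_sd = 0.6),
                         noise_scale = 1) {
  structure(list(fractions = fractions, pta = pta, caloric = caloric,
                 cvemp = cvemp, ovemp = ovemp, vhit = vhit,
                 latencies = latencies, noise_scale = noise_scale),
            class = "effect_model")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# reference whole-ear weighting of the two compartments (default phantom
# fluid shares: cochlea ~52%, vestibule ~48%)
.compartment_weights <- c(cochlea = 0.52, vestibule = 0.48)

# truth-based hydrops grades from requested fractions (same thresholds as
# the image-based grading)
truth_grades <- function(frac_coch, frac_vest, detection_floor = 0.05) {
  list(
    cochlear = grade_cochlea(frac_coch, 1 - frac_coch, detection_floor),
    vestibular = grade_vestibule(clamp(frac_vest, 0, 1))
  )
}

#' Generate a synthetic cohort of subjects with known ground truth
#'
#' Draws per-subject endolymph fractions per the group effect model,
#' assigns the clinically leading side pseudorandomly, and generates the
#' neurotology record through the monotone links. Images are not
#' materialised here (see [subject_phantom_spec()] /
#' [make_phantom_subject()]); the returned table carries everything the
#' statistics stages need, including the ground-truth fractions and
#' truth-based hydrops grades.
#'
#' @param group_sizes named integer vector, e.g.
#'   `c(VM = 25, MD = 29, "VM-MD" = 8)`; all sizes >= 0.
#' @param model an [effect_model()].
#' @param seed integer master seed.
#' @return tibble, one row per subject.
#' @export
generate_cohort <- function(group_sizes = c(VM = 25, MD = 29, `VM-MD` = 8),
                            model = effect_model(), seed = 1L) {
  if (any(group_sizes < 0)) stop("group sizes must be >= 0")
  groups <- rep(names(group_sizes), times = group_sizes)
  n <- length(groups)
  if (n == 0L) {
    return(tibble::tibble(id = character(0), group = character(0)))
  }
  ns <- model$noise_scale
  rows <- withr::with_seed(substream_seed(seed, "cohort"),
                           purrr::map_dfr(seq_len(n), function(i) {
    g <- groups[i]
    fr <- model$fractions[[g]]
    leading <- sample(c("left", "right"), 1L)
    f_vest_i <- clamp(stats::rnorm(1, fr[["ipsi_mean"]], fr[["ipsi_sd"]]), 0.01, 0.75)
    f_vest_c <- clamp(stats::rnorm(1, fr[["contra_mean"]], fr[["contra_sd"]]), 0.01, 0.75)
    f_coch_i <- clamp(stats::rnorm(1, fr[["ipsi_mean"]], fr[["ipsi_sd"]]), 0.01, 0.75)
    f_coch_c <- clamp(stats::rnorm(1, fr[["contra_mean"]], fr[["contra_sd"]]), 0.01, 0.75)
    w <- .compartment_weights
    wf_i <- w[["cochlea"]] * f_coch_i + w[["vestibule"]] * f_vest_i
    wf_c <- w[["cochlea"]] * f_coch_c + w[["vestibule"]] * f_vest_c

    pta_i <- model$pta[["base"]] + model$pta[["slope"]] * wf_i +
      stats::rnorm(1, 0, model$pta[["sd"]] * ns)
    pta_c <- model$pta[["base"]] + model$pta[["slope"]] * wf_c +
      stats::rnorm(1, 0, model$pta[["sd"]] * ns)
    spv <- function(wf) max(model$caloric[["base"]] * (1 - model$caloric[["slope"]] * wf) +
                              stats::rnorm(1, 0, model$caloric[["sd"]] * ns), 0)
    spv_i <- spv(wf_i); spv_c <- spv(wf_c)
    amp <- function(base, slope, sd, f) max(base - slope * f + stats::rnorm(1, 0, sd * ns), 0.1)
    cv_i <- amp(model$cvemp[["base"]], model$cvemp[["slope"]], model$cvemp[["sd"]], f_vest_i)
    cv_c <- amp(model$cvemp[["base"]], model$cvemp[["slope"]], model$cvemp[["sd"]], f_vest_c)
    ov_i <- amp(model$ovemp[["base"]], model$ovemp[["slope"]], model$ovemp[["sd"]], f_vest_i)
    ov_c <- amp(model$ovemp[["base"]], model$ovemp[["slope"]], model$ovemp[["sd"]], f_vest_c)
    gain <- function(f) clamp(model$vhit[["base"]] - model$vhit[["slope"]] * f +
                                stats::rnorm(1, 0, model$vhit[["sd"]] * ns), 0.2, 1.2)
    vh_i <- gain(f_vest_i); vh_c <- gain(f_vest_c)
    lat <- model$latencies
    p13 <- stats::rnorm(2, lat[["cvemp_p13_mean"]], lat[["cvemp_p13_sd"]] * ns)
    n10 <- stats::rnorm(2, lat[["ovemp_n10_mean"]], lat[["ovemp_n10_sd"]] * ns)

    to_lr <- function(ipsi, contra) {
      if (leading == "right") c(right = ipsi, left = contra)
      else c(right = contra, left = ipsi)
    }
    warm <- model$caloric[["warm_share"]]
    spv_lr <- to_lr(spv_i, spv_c)
    pta_lr <- to_lr(pta_i, pta_c)
    cv_lr <- to_lr(cv_i, cv_c)
    ov_lr <- to_lr(ov_i, ov_c)
    vh_lr <- to_lr(vh_i, vh_c)
    fv_lr <- to_lr(f_vest_i, f_vest_c)
    fc_lr <- to_lr(f_coch_i, f_coch_c)
    tg <- truth_grades(f_coch_i, f_vest_i)
    tg_c <- truth_grades(f_coch_c, f_vest_c)

    tibble::tibble(
      id = sprintf("S%03d", i), group = g, leading_side = leading,
      frac_coch_ipsi = f_coch_i, frac_coch_contra = f_coch_c,
      frac_vest_ipsi = f_vest_i, frac_vest_contra = f_vest_c,
      frac_ear_ipsi = wf_i, frac_ear_contra = wf_c,
      frac_coch_right = fc_lr[["right"]], frac_coch_left = fc_lr[["left"]],
      frac_vest_right = fv_lr[["right"]], frac_vest_left = fv_lr[["left"]],
      pta_right = pta_lr[["right"]], pta_left = pta_lr[["left"]],
      caloric_r30 = spv_lr[["right"]] * (1 - warm),
      caloric_r44 = spv_lr[["right"]] * warm,
      caloric_l30 = spv_lr[["left"]] * (1 - warm),
      caloric_l44 = spv_lr[["left"]] * warm,
      cvemp_p13_amp_right = cv_lr[["right"]], cvemp_p13_amp_left = cv_lr[["left"]],
      cvemp_p13_lat_right = p13[1], cvemp_p13_lat_left = p13[2],
      ovemp_n10_amp_right = ov_lr[["right"]], ovemp_n10_amp_left = ov_lr[["left"]],
      ovemp_n10_lat_right = n10[1], ovemp_n10_lat_left = n10[2],
      vhit_gain_right = vh_lr[["right"]], vhit_gain_left = vh_lr[["left"]],
      truth_coch_grade_ipsi = tg$cochlear, truth_vest_grade_ipsi = tg$vestibular,
      truth_coch_grade_contra = tg_c$cochlear, truth_vest_grade_contra = tg_c$vestibular,
      eh_present = tg$cochlear > 0L | tg$vestibular > 0L |
        tg_c$cochlear > 0L | tg_c$vestibular > 0L
    )
  }))
  rows
}

#' Phantom spec for one cohort subject
#'
#' Maps a cohort row's per-side fractions onto a base [phantom_spec()] and
#' derives a per-subject seed from the row id, so subject images are
#' reproducible independently of generation order.
#'
#' @param row one-row tibble from [generate_cohort()].
#' @param base_spec the shared [phantom_spec()] (grid, geometry, noise).
#' @param seed cohort master seed.
#' @return a [phantom_spec()].
#' @export
subject_phantom_spec <- function(row, base_spec = phantom_spec(), seed = 1L) {
  sp <- base_spec
  sp$vestibule$frac <- c(row$frac_vest_left, row$frac_vest_right)
  sp$cochlea$frac <- c(row$frac_coch_left, row$frac_coch_right)
  sp$seed <- substream_seed(seed, row$id)
  validate_phantom_spec(sp)
  sp
}

#' Write a cohort table to CSV
#'
#' @param cohort tibble from [generate_cohort()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Write a subject's sequence triplet and truth labels as NIfTI
#'
#' @param subject list from [make_phantom_subject()].
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_subject_niftis <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mrc = file.path(dir, "mrc.nii.gz"),
    ppi = file.path(dir, "ppi.nii.gz"),
    pei = file.path(dir, "pei.nii.gz"),
    labels = file.path(dir, "truth_labels.nii.gz"),
    compartments = file.path(dir, "truth_compartments.nii.gz")
  )
  write_volume(subject$triplet$mrc, paths[["mrc"]])
  write_volume(subject$triplet$ppi, paths[["ppi"]])
  write_volume(subject$triplet$pei, paths[["pei"]])
  write_volume(subject$truth$label, paths[["labels"]])
  write_volume(subject$truth$compartment, paths[["compartments"]])
  invisible(paths)
}
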