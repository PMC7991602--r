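#' Jongkees caloric asymmetry from bithermal slow-phase velocities
#'
#' `100 * [(R30 + R44) - (L30 + L44)] / [(R30 + R44) + (L30 + L44)]`
#' computed from the slow-phase velocities of caloric nystagmus after 30 °C
#' cold and 44 °C warm irrigation of each ear. The absolute value is the
#' asymmetry ratio (AR); the sign indicates the weaker side (positive:
#' right responses stronger, left side weaker). Invariant under scaling
#' all four responses by a positive constant.
#'
#' @param r30,r44,l30,l44 slow-phase velocities, degrees/s, all >= 0.
#' @return tibble with `ar_pct` (absolute), `signed_pct` and `weaker_side`
#'   (`"left"`, `"right"` or `"none"`).
#' @export
caloric_asymmetry <- function(r30, r44, l30, l44) {
  v <- c(r30, r44, l30, l44)
  stopifnot(all(v >= 0))
  tot <- sum(v)
  if (tot == 0) stop("bilateral areflexia, AR undefined")
  signed <- 100 * ((r30 + r44) - (l30 + l44)) / tot
  tibble::tibble(
    ar_pct = abs(signed),
    signed_pct = signed,
    weaker_side = if (signed > 0) "left" else if (signed < 0) "right" else "none"
  )
}

#' Vestibular paresis flag from the caloric asymmetry ratio
#'
#' Paresis is a strictly greater than 35% asymmetry between the right- and
#' left-sided responses.
#'
#' @param ar_pct absolute asymmetry ratio, percent, >= 0.
#' @return logical.
#' @export
is_vestibular_paresis <- function(ar_pct) {
  stopifnot(all(ar_pct >= 0))
  ar_pct > 35
}

#' VEMP amplitude asymmetry ratio
#'
#' `AR = 100 * (larger - smaller) / (larger + smaller)` of the two sides'
#' response amplitudes; scale-invariant by construction.
#'
#' @param larger,smaller response amplitudes with
#'   `larger >= smaller >= 0` and `larger > 0`.
#' @return percentage in `[0, 100]`.
#' @export
vemp_ar <- function(larger, smaller) {
  stopifnot(all(larger >= smaller), all(smaller >= 0), all(larger > 0))
  100 * (larger - smaller) / (larger + smaller)
}

#' Thresholds for the deficit classification
#'
#' All cut-offs are configurable; the defaults follow the abnormality
#' definitions used for the cohort cross-tabulations: initial PTA >= 25 dB
#' (cochlear), caloric AR >= 35%, cVEMP p13 / oVEMP n10 amplitude
#' AR >= 40%, and a vHIT horizontal gain below `n_sd` standard deviations
#' of the reference mean (the reference gain table is supplied here since
#' age-matched norms are device-specific).
#'
#' @param pta_db,caloric_ar_pct,vemp_ar_pct numeric cut-offs.
#' @param vhit_reference list with `gain_mean`, `gain_sd`, `n_sd`.
#' @return a `neurotology_thresholds` list.
#' @export
neurotology_thresholds <- function(pta_db = 25,
                                   caloric_ar_pct = 35,
                                   vemp_ar_pct = 40,
                                   vhit_reference = list(gain_mean = 0.96,
                                                         gain_sd = 0.07,
                                                         n_sd = 2)) {
  structure(list(pta_db = pta_db, caloric_ar_pct = caloric_ar_pct,
                 vemp_ar_pct = vemp_ar_pct, vhit_reference = vhit_reference),
            class = "neurotology_thresholds")
}

required_neurotology_fields <- c(
  "pta_right", "pta_left", "caloric_r30", "caloric_r44", "caloric_l30",
  "caloric_l44", "cvemp_p13_amp_right", "cvemp_p13_amp_left",
  "ovemp_n10_amp_right", "ovemp_n10_amp_left", "vhit_gain_right",
  "vhit_gain_left"
)

#' Classify audio-vestibular deficits from a neurotology record
#'
#' A cochlear deficit is present when either side's PTA reaches the PTA
#' cut-off; a vestibular deficit when the caloric AR, a VEMP amplitude AR
#' (cVEMP p13 or oVEMP n10) or an abnormal vHIT gain is found; both
#' together make a vestibulocochlear deficit. Laterality collects the
#' implicated side(s) (`bilateral` when both). A pure function of the
#' record and thresholds. VEMP latencies are recorded in cohort tables but
#' do not enter the classification.
#'
#' @param record one-row data frame (or named list) with the fields in
#'   `hydroquant:::required_neurotology_fields` (PTA per side in dB,
#'   caloric SPVs in degrees/s, VEMP amplitudes per side, vHIT gain per
#'   side).
#' @param thresholds a [neurotology_thresholds()].
#' @return tibble with `category` (`normal`, `vestibular`, `cochlear`,
#'   `vestibulocochlear`) and `laterality` (`normal`, `right`, `left`,
#'   `bilateral`).
#' @export
classify_deficits <- function(record, thresholds = neurotology_thresholds()) {
  record <- as.list(record)
  missing_fields <- setdiff(required_neurotology_fields, names(record))
  missing_fields <- union(missing_fields,
                          names(Filter(function(x) length(x) != 1 || is.na(x),
                                       record[intersect(names(record),
                                                        required_neurotology_fields)])))
  if (length(missing_fields)) {
    stop("incomplete neurotology record; missing: ",
         paste(sort(missing_fields), collapse = ", "))
  }
  th <- thresholds
  sides <- character(0)

  # cochlear: PTA at or above cut-off on either side
  coch_sides <- c("right", "left")[c(record$pta_right >= th$pta_db,
                                     record$pta_left >= th$pta_db)]

  # vestibular: caloric AR, VEMP ARs, vHIT gain
  vest_sides <- character(0)
  cal <- caloric_asymmetry(record$caloric_r30, record$caloric_r44,
                           record$caloric_l30, record$caloric_l44)
  if (cal$ar_pct >= th$caloric_ar_pct) vest_sides <- c(vest_sides, cal$weaker_side)
  vemp_side <- function(right, left) {
    if (max(right, left) <= 0) return(character(0))
    ar <- vemp_ar(max(right, left), min(right, left))
    if (ar >= th$vemp_ar_pct) {
      if (right < left) "right" else "left"
    } else character(0)
  }
  vest_sides <- c(vest_sides,
                  vemp_side(record$cvemp_p13_amp_right, record$cvemp_p13_amp_left),
                  vemp_side(record$ovemp_n10_amp_right, record$ovemp_n10_amp_left))
  vr <- th$vhit_reference
  gain_floor <- vr$gain_mean - vr$n_sd * vr$gain_sd
  if (record$vhit_gain_right < gain_floor) vest_sides <- c(vest_sides, "right")
  if (record$vhit_gain_left < gain_floor) vest_sides <- c(vest_sides, "left")
  vest_sides <- setdiff(unique(vest_sides), "none")

  category <- if (length(coch_sides) && length(vest_sides)) "vestibulocochlear"
    else if (length(coch_sides)) "cochlear"
    else if (length(vest_sides)) "vestibular"
    else "normal"
  sides <- unique(c(coch_sides, vest_sides))
  laterality <- if (category == "normal") "normal"
    else if (length(sides) > 1) "bilateral"
    else sides
  tibble::tibble(category = category, laterality = laterality)
}
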