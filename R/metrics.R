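#' Volume of a binary mask in cubic millimetres
#'
#' @param mask logical array or logical `volume`.
#' @param voxel_mm voxel edge length(s), mm (taken from the volume if one
#'   is given).
#' @return volume in mm^3.
#' @export
els_volume <- function(mask, voxel_mm = NULL) {
  if (is_volume(mask)) {
    voxel_mm <- mask$voxel_mm
    mask <- mask$data
  }
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  sum(mask) * prod(voxel_mm)
}

#' Asymmetry index of a right/left volume pair
#'
#' `AI = 100 * (right - left) / (right + left)` in percent; defined as 0
#' when both sides are 0. Antisymmetric under swapping the sides.
#'
#' @param els_r,els_l right and left volumes (mm^3), both >= 0.
#' @return signed percentage in `[-100, 100]`.
#' @export
asymmetry_index <- function(els_r, els_l) {
  stopifnot(els_r >= 0, els_l >= 0)
  tot <- els_r + els_l
  ifelse(tot == 0, 0, 100 * (els_r - els_l) / tot)
}

#' Side difference and its TFS ratio
#'
#' `Diff = |ipsilateral - contralateral|` in mm^3 and
#' `Diff/TFS = 100 * Diff / TFS` in percent, the TFS being the mean total
#' fluid space of the two sides.
#'
#' @param els_i,els_c ipsilateral and contralateral ELS volumes (mm^3).
#' @param tfs_mean mean TFS (mm^3), > 0.
#' @return named numeric `c(diff_mm3, diff_tfs_pct)`.
#' @export
diff_and_ratio <- function(els_i, els_c, tfs_mean) {
  stopifnot(tfs_mean > 0)
  d <- abs(els_i - els_c)
  c(diff_mm3 = d, diff_tfs_pct = 100 * d / tfs_mean)
}

#' Vestibular hydrops grade from an area ratio
#'
#' Semi-quantitative grading of vestibular endolymphatic hydrops from the
#' ELS/TFS area ratio at the grading slice: below 1/3 is grade 0 (none),
#' from 1/3 up to and including 50% grade 1 (mild), strictly above 50%
#' grade 2 (severe).
#'
#' @param area_ratio fraction in `[0, 1]` (vectorised).
#' @return integer grade(s) 0, 1 or 2.
#' @export
grade_vestibule <- function(area_ratio) {
  stopifnot(all(area_ratio >= 0 & area_ratio <= 1))
  ifelse(area_ratio < 1 / 3, 0L, ifelse(area_ratio <= 0.5, 1L, 2L))
}

#' Cochlear hydrops grade from duct and scala-vestibuli areas
#'
#' Grade 0 when the ELS area of the cochlear duct is below the detection
#' floor; grade 1 (mild) when it is detectable but no larger than the
#' scala-vestibuli area; grade 2 (severe) when the duct area exceeds it.
#'
#' @param duct_area ELS-classified area of the cochlear duct.
#' @param scala_vestibuli_area remaining (perilymphatic) area at the slice.
#' @param detection_floor minimum duct area counted as hydrops (same
#'   units).
#' @return integer grade 0, 1 or 2 (vectorised).
#' @export
grade_cochlea <- function(duct_area, scala_vestibuli_area, detection_floor = 0) {
  stopifnot(all(duct_area >= 0), all(scala_vestibuli_area >= 0))
  ifelse(duct_area <= 0 | duct_area < detection_floor, 0L,
         ifelse(duct_area <= scala_vestibuli_area, 1L, 2L))
}

# side label array from the grid's left-right midplane (axis 3):
# 1 = left (lower indices), 2 = right
side_regions <- function(d) {
  side <- array(1L, dim = d)
  side[, , seq_len(d[3]) > d[3] / 2] <- 2L
  side
}

# per-axial-slice (axis 2) areas of a mask restricted to a region
slice_areas <- function(mask, region) {
  apply(mask & region, 2, sum)
}

#' Select the grading slices for a subject side
#'
#' Cochlear grading uses the axial slice with the largest cochlear
#' total-fluid cross-section (a mid-modiolar surrogate); vestibular grading
#' uses the lowest axial slice whose vestibular fluid cross-section exceeds
#' half its maximum — the canal-free surrogate of the "lowest slice with
#' the lateral semicircular canal still visible" rule, since the phantom
#' omits the canals. Ties break toward the lower slice index.
#'
#' Grading is performed at acquisition slice thickness: when the analysis
#' grid is an upsampled version of the acquired grid (`slab_voxels` > 1,
#' normally the preprocessing rescale factor), areas are aggregated over
#' slabs of `slab_voxels` consecutive analysis slices, which correspond to
#' one acquired slice each.
#'
#' @param hull_mask logical array, the TFS hull.
#' @param compartment integer array (1 cochlea, 2 vestibule) on the same
#'   grid.
#' @param side_mask logical array selecting one side.
#' @param slab_voxels analysis slices per acquired slice (>= 1).
#' @return named integer `c(cochlear_slice, vestibular_slice)` — the first
#'   analysis slice of each selected slab — with the full slab index sets
#'   in attribute `slab_indices`.
#' @export
select_grading_slices <- function(hull_mask, compartment, side_mask,
                                  slab_voxels = 1L) {
  slab_voxels <- max(1L, as.integer(slab_voxels))
  coch_a <- slab_sums(slice_areas(hull_mask & side_mask, compartment == 1L), slab_voxels)
  vest_a <- slab_sums(slice_areas(hull_mask & side_mask, compartment == 2L), slab_voxels)
  if (all(coch_a == 0)) stop("empty cochlear compartment; cannot select a grading slice")
  if (all(vest_a == 0)) stop("empty vestibular compartment; cannot select a grading slice")
  cs <- which.max(coch_a)  # which.max already breaks ties low
  vs <- which(vest_a > max(vest_a) / 2)[1]
  n <- dim(hull_mask)[2]
  slab_idx <- function(k) ((k - 1L) * slab_voxels + 1L):min(k * slab_voxels, n)
  out <- c(cochlear_slice = slab_idx(cs)[1], vestibular_slice = slab_idx(vs)[1])
  attr(out, "slab_indices") <- list(cochlear = slab_idx(cs),
                                    vestibular = slab_idx(vs))
  out
}

# sums of consecutive groups of `k` elements (last group may be shorter)
slab_sums <- function(x, k) {
  if (k <= 1L) return(x)
  grp <- (seq_along(x) - 1L) %/% k
  as.numeric(tapply(x, grp, sum))
}

#' Per-side, per-compartment ELS measures
#'
#' Tabulates ELS and TFS volumes and their percentage ratio for the whole
#' inner ear, the cochlea and the vestibule on each side.
#'
#' @param els an `els_mask` with compartments split
#'   (see [split_compartments()]).
#' @param hull the `binary_hull` on the same grid.
#' @param compartment integer compartment array (1 cochlea, 2 vestibule).
#' @return tibble with columns `side`, `scope`, `els_mm3`, `tfs_mm3`,
#'   `els_tfs_pct`.
#' @export
els_measures <- function(els, hull, compartment) {
  stopifnot(inherits(els, "els_mask"), inherits(hull, "binary_hull"))
  d <- dim(els$mask$data)
  vox3 <- prod(els$mask$voxel_mm)
  side <- side_regions(d)
  rows <- tidyr::expand_grid(side = c("left", "right"),
                             scope = c("ear", "cochlea", "vestibule"))
  out <- purrr::map2_dfr(rows$side, rows$scope, function(s, sc) {
    sm <- side == (if (s == "left") 1L else 2L)
    reg <- switch(sc,
                  ear = array(TRUE, d),
                  cochlea = compartment == 1L,
                  vestibule = compartment == 2L)
    els_n <- if (sc == "ear") sum(els$mask$data & sm) else
      sum(els$mask$data & sm & reg)
    tfs_n <- sum(hull$mask$data & sm & reg)
    tibble::tibble(
      els_mm3 = els_n * vox3, tfs_mm3 = tfs_n * vox3,
      els_tfs_pct = if (tfs_n > 0) 100 * els_n / tfs_n else NA_real_
    )
  })
  dplyr::bind_cols(rows, out)
}

#' Pairwise (ipsilateral/contralateral) ELS asymmetry measures
#'
#' Derives, per scope, the mean ELS, the side difference `Diff`, its TFS
#' ratio and the signed right-minus-left asymmetry index from the per-side
#' measures.
#'
#' @param measures tibble from [els_measures()].
#' @param leading_side `"left"` or `"right"` — the clinically leading
#'   (ipsilateral) side.
#' @return tibble with one row per scope.
#' @export
pair_measures <- function(measures, leading_side = c("right", "left")) {
  leading_side <- match.arg(leading_side)
  measures |>
    tidyr::pivot_wider(names_from = "side",
                       values_from = c("els_mm3", "tfs_mm3", "els_tfs_pct")) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      leading_side = leading_side,
      els_ipsi_mm3 = if (leading_side == "right") .data$els_mm3_right else .data$els_mm3_left,
      els_contra_mm3 = if (leading_side == "right") .data$els_mm3_left else .data$els_mm3_right,
      els_mean_mm3 = (.data$els_mm3_right + .data$els_mm3_left) / 2,
      tfs_mean_mm3 = (.data$tfs_mm3_right + .data$tfs_mm3_left) / 2,
      diff_mm3 = abs(.data$els_ipsi_mm3 - .data$els_contra_mm3),
      diff_tfs_pct = 100 * .data$diff_mm3 / .data$tfs_mean_mm3,
      ai_pct = asymmetry_index(.data$els_mm3_right, .data$els_mm3_left)
    ) |>
    dplyr::ungroup()
}

#' Grade hydrops for both sides of a subject
#'
#' Applies the slice-selection rules and the area-ratio grading to the
#' segmented ELS: the vestibular grade from the ELS/TFS area ratio at the
#' vestibular grading slice, the cochlear grade by comparing the
#' ELS-classified duct area against the remaining perilymphatic area at
#' the mid-modiolar surrogate slice (detection floor: fraction of the
#' slice's cochlear fluid area).
#'
#' @param els an `els_mask` with compartments split.
#' @param hull the `binary_hull`.
#' @param compartment integer compartment array (1 cochlea, 2 vestibule).
#' @param detection_floor cochlear detection floor as a fraction of the
#'   cochlear slice fluid area (default 0.05).
#' @param slab_voxels analysis slices per acquired slice (grading is done
#'   at acquisition slice thickness; see [select_grading_slices()]).
#' @return tibble with one row per side: grading slices, area ratios and
#'   grades.
#' @export
grade_subject <- function(els, hull, compartment, detection_floor = 0.05,
                          slab_voxels = 1L) {
  d <- dim(els$mask$data)
  side <- side_regions(d)
  purrr::map_dfr(c("left", "right"), function(s) {
    sm <- side == (if (s == "left") 1L else 2L)
    sl <- select_grading_slices(hull$mask$data, compartment, sm, slab_voxels)
    slabs <- attr(sl, "slab_indices")
    area <- function(mask, idx, comp_id) {
      sum(mask[, idx, , drop = FALSE] & sm[, idx, , drop = FALSE] &
            (compartment[, idx, , drop = FALSE] == comp_id))
    }
    vest_tfs <- area(hull$mask$data, slabs$vestibular, 2L)
    vest_els <- area(els$mask$data, slabs$vestibular, 2L)
    coch_tfs <- area(hull$mask$data, slabs$cochlear, 1L)
    coch_els <- area(els$mask$data, slabs$cochlear, 1L)
    v_ratio <- if (vest_tfs > 0) vest_els / vest_tfs else 0
    tibble::tibble(
      side = s,
      cochlear_slice = unname(sl["cochlear_slice"]),
      vestibular_slice = unname(sl["vestibular_slice"]),
      vestibular_area_ratio = v_ratio,
      vestibular_grade = grade_vestibule(min(v_ratio, 1)),
      cochlear_duct_area = coch_els,
      scala_vestibuli_area = coch_tfs - coch_els,
      cochlear_grade = grade_cochlea(coch_els, coch_tfs - coch_els,
                                     detection_floor * coch_tfs)
    )
  })
}

#' Plot per-scope ELS measures
#'
#' @param object tibble from [pair_measures()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.els_measures <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object, c("els_ipsi_mm3", "els_contra_mm3"),
    names_to = "side", values_to = "els"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scope, y = .data$els, fill = .data$side)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(y = "ELS volume [mm³]", x = NULL, fill = NULL)
}
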