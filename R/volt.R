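#' VOLT ensemble configuration
#'
#' The volumetric local thresholding ensemble runs two local threshold
#' algorithms (Niblack, `t = mu_w + k * sd_w`; local mean,
#' `t = mu_w + offset`) at two window radii along the three orthogonal
#' grid orientations — 12 classifiers. A voxel receives one vote per
#' classifier whose local threshold it falls strictly below (endolymph is
#' the dark foreground), and voxels with at least `vote_cutoff` votes are
#' classified endolymph.
#'
#' @param window_radii integer window radii in voxels on the analysis grid
#'   (window edge `2r + 1`); default `c(6, 10)`.
#' @param niblack_k Niblack weight on the window standard deviation
#'   (negative for dark foreground).
#' @param mean_offset additive offset of the local-mean threshold.
#' @param vote_cutoff minimum number of votes (of 12) classifying
#'   endolymph; default 11.
#' @param mode `"2d"` (the default: thresholds computed slicewise, in the
#'   plane perpendicular to each orientation) or `"3d"` (cubic windows;
#'   provided as a variant, not the default reading).
#' @return a `volt_config` list.
#' @export
volt_config <- function(window_radii = c(6L, 10L),
                        niblack_k = -0.2,
                        mean_offset = 0,
                        vote_cutoff = 11L,
                        mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  window_radii <- as.integer(window_radii)
  stopifnot(all(window_radii >= 1L))
  n_votes <- 2L * length(window_radii) * 3L
  vote_cutoff <- as.integer(vote_cutoff)
  if (vote_cutoff < 1L || vote_cutoff > n_votes) {
    stop(sprintf("vote_cutoff must lie in [1, %d]", n_votes))
  }
  structure(list(window_radii = window_radii, niblack_k = niblack_k,
                 mean_offset = mean_offset, vote_cutoff = vote_cutoff,
                 mode = mode, n_classifiers = n_votes),
            class = "volt_config")
}

# cumulative sum along one axis of a 3D array (vectorised over the others)
cumsum_axis <- function(a, axis) {
  perm <- c(setdiff(1:3, axis), axis)
  ap <- aperm(a, perm)
  d <- dim(ap)
  M <- matrix(ap, ncol = d[3])
  if (ncol(M) > 1L) for (i in 2:ncol(M)) M[, i] <- M[, i] + M[, i - 1]
  aperm(array(M, d), order(perm))
}

# pad a summed-area table with a leading zero slab along given axes
pad_zero <- function(a, axes) {
  d <- dim(a)
  dd <- d + as.integer(1:3 %in% axes)
  out <- array(0, dim = dd)
  out[(1:3 %in% axes)[1] + seq_len(d[1]),
      (1:3 %in% axes)[2] + seq_len(d[2]),
      (1:3 %in% axes)[3] + seq_len(d[3])] <- a
  out
}

# windowed box sums over the window axes (clipped at borders) from a
# zero-padded SAT; `axes` are the axes the SAT was accumulated along
box_from_sat <- function(sat_padded, d, axes, r) {
  lo <- hi <- vector("list", 3)
  for (ax in 1:3) {
    if (ax %in% axes) {
      hi[[ax]] <- pmin(seq_len(d[ax]) + r, d[ax]) + 1L
      lo[[ax]] <- pmax(seq_len(d[ax]) - r - 1L, 0L) + 1L
    } else {
      lo[[ax]] <- hi[[ax]] <- seq_len(d[ax])
    }
  }
  g <- function(i1, i2, i3) sat_padded[i1, i2, i3, drop = FALSE]
  a1 <- axes[1]; a2 <- axes[2]
  pick <- function(which1, which2) {
    ii <- list(hi[[1]], hi[[2]], hi[[3]])
    ii[[a1]] <- if (which1 == "lo") lo[[a1]] else hi[[a1]]
    ii[[a2]] <- if (which2 == "lo") lo[[a2]] else hi[[a2]]
    g(ii[[1]], ii[[2]], ii[[3]])
  }
  pick("hi", "hi") - pick("lo", "hi") - pick("hi", "lo") + pick("lo", "lo")
}

# 3D variant: box sums over all three axes
box3_from_sat <- function(sat_padded, d, r) {
  hi <- lapply(1:3, function(ax) pmin(seq_len(d[ax]) + r, d[ax]) + 1L)
  lo <- lapply(1:3, function(ax) pmax(seq_len(d[ax]) - r - 1L, 0L) + 1L)
  g <- function(s1, s2, s3) {
    ii <- mapply(function(s, h, l) if (s) h else l, c(s1, s2, s3), hi, lo,
                 SIMPLIFY = FALSE)
    sat_padded[ii[[1]], ii[[2]], ii[[3]], drop = FALSE]
  }
  g(TRUE, TRUE, TRUE) - g(FALSE, TRUE, TRUE) - g(TRUE, FALSE, TRUE) -
    g(TRUE, TRUE, FALSE) + g(FALSE, FALSE, TRUE) + g(FALSE, TRUE, FALSE) +
    g(TRUE, FALSE, FALSE) - g(FALSE, FALSE, FALSE)
}

# masked window statistics (count, mean, sd) for one orientation/radius;
# NA voxels (outside the fused hull) are excluded from the statistics
window_stats <- function(sats, d, axes, r) {
  if (length(axes) == 2L) {
    cnt <- box_from_sat(sats$w, d, axes, r)
    s1 <- box_from_sat(sats$s1, d, axes, r)
    s2 <- box_from_sat(sats$s2, d, axes, r)
  } else {
    cnt <- box3_from_sat(sats$w, d, r)
    s1 <- box3_from_sat(sats$s1, d, r)
    s2 <- box3_from_sat(sats$s2, d, r)
  }
  mu <- ifelse(cnt > 0, s1 / pmax(cnt, 1), NA_real_)
  vr <- ifelse(cnt > 0, s2 / pmax(cnt, 1) - mu^2, NA_real_)
  list(count = cnt, mean = mu, sd = sqrt(pmax(vr, 0)))
}

sats_for_axes <- function(w, av, av2, axes) {
  acc <- function(a) {
    for (ax in axes) a <- cumsum_axis(a, ax)
    pad_zero(a, axes)
  }
  list(w = acc(w), s1 = acc(av), s2 = acc(av2))
}

#' Slicewise local thresholding along one orientation
#'
#' For every 2D slice perpendicular to `axis`, computes the local threshold
#' in a `(2r+1)^2` window around each voxel — Niblack
#' `t = mu_w + k * sd_w` or local mean `t = mu_w + offset` — and marks a
#' voxel as an endolymph vote when its intensity is strictly below the
#' threshold. Sentinel (`NA`, outside-hull) voxels never vote and are
#' excluded from the window statistics; windows are clipped at slice
#' borders (no padding values are invented).
#'
#' @param fused fused Mi2 `volume` (`NA` outside the hull) from [fuse()].
#' @param axis orientation (1, 2 or 3): slices are perpendicular to it.
#' @param algorithm `"niblack"` or `"mean"`.
#' @param radius window radius in voxels.
#' @param k,offset algorithm parameters (see [volt_config()]).
#' @return logical vote array with the volume's dimensions.
#' @export
local_threshold_slicewise <- function(fused, axis, algorithm = c("niblack", "mean"),
                                      radius, k = -0.2, offset = 0) {
  algorithm <- match.arg(algorithm)
  stopifnot(is_volume(fused), axis %in% 1:3, radius >= 1)
  d <- dim(fused$data)
  inplane <- setdiff(1:3, axis)
  if (radius > max(d[inplane])) {
    stop(sprintf("window radius %d exceeds the slice extent %s", radius,
                 paste(d[inplane], collapse = "x")))
  }
  w <- !is.na(fused$data)
  av <- ifelse(w, fused$data, 0)
  sats <- sats_for_axes(w * 1, av, av * av, inplane)
  st <- window_stats(sats, d, inplane, as.integer(radius))
  thr <- if (algorithm == "niblack") st$mean + k * st$sd else st$mean + offset
  vote <- w & !is.na(thr) & (fused$data < thr)
  vote
}

# all 12 (or however many the config defines) classifier vote arrays, in
# the fixed provenance order: orientation (1..3) x algorithm
# (niblack, mean) x radius (ascending)
volt_classifications <- function(fused, cfg = volt_config()) {
  stopifnot(is_volume(fused), inherits(cfg, "volt_config"))
  d <- dim(fused$data)
  w <- !is.na(fused$data)
  av <- ifelse(w, fused$data, 0)
  out <- list()
  prov <- list()
  for (axis in 1:3) {
    inplane <- setdiff(1:3, axis)
    axes <- if (cfg$mode == "2d") inplane else 1:3
    sats <- sats_for_axes(w * 1, av, av * av, axes)
    for (alg in c("niblack", "mean")) {
      for (r in cfg$window_radii) {
        if (r > max(d[inplane])) {
          stop(sprintf("window radius %d exceeds the slice extent", r))
        }
        st <- window_stats(sats, d, axes, r)
        thr <- if (alg == "niblack") st$mean + cfg$niblack_k * st$sd
               else st$mean + cfg$mean_offset
        out[[length(out) + 1L]] <- w & !is.na(thr) & (fused$data < thr)
        prov[[length(prov) + 1L]] <- tibble::tibble(
          orientation = axis, algorithm = alg, radius = r
        )
      }
    }
    if (cfg$mode == "3d") break  # 3D windows are orientation-independent
  }
  if (cfg$mode == "3d") {
    # replicate the single orientation pass to keep the 12-member ensemble
    out <- rep(out, 3L)
    prov <- rep(prov, 3L)
  }
  attr(out, "provenance") <- dplyr::bind_rows(prov)
  out
}

#' Aggregate classifier votes
#'
#' Voxelwise sum of the binary classifications, in the fixed provenance
#' order (a permutation of the classifiers leaves the counts unchanged).
#'
#' @param classifications list of logical arrays from
#'   [volt_classifications()].
#' @param n_expected expected ensemble size (default 12).
#' @return an `aggregation_volume`: `votes` (integer `volume`) and the
#'   provenance table.
#' @export
aggregate_votes <- function(classifications, n_expected = 12L) {
  if (length(classifications) != n_expected) {
    stop(sprintf("expected %d classifications, got %d", n_expected,
                 length(classifications)))
  }
  d <- dim(classifications[[1]])
  votes <- array(0L, dim = d)
  for (cl in classifications) {
    if (!identical(dim(cl), d)) stop("classification grids differ")
    votes <- votes + cl
  }
  structure(list(votes = votes,
                 provenance = attr(classifications, "provenance")),
            class = "aggregation_volume")
}

#' Classify the endolymphatic space from the vote aggregation
#'
#' `mask = (votes >= cutoff) & hull`: low Mi2 intensities collect votes
#' from the dark-foreground classifiers, and the cut-off turns the
#' 0..12-vote map into the binary ELS mask.
#'
#' @param agg an `aggregation_volume`.
#' @param cfg a [volt_config()] (supplies the cut-off).
#' @param hull the `binary_hull` restricting the classification.
#' @param voxel_mm voxel size for the output mask.
#' @return an `els_mask`: `mask` (`volume`, logical) plus empty compartment
#'   slots (see [split_compartments()]).
#' @export
classify_els <- function(agg, cfg, hull, voxel_mm = hull$mask$voxel_mm) {
  stopifnot(inherits(agg, "aggregation_volume"), inherits(hull, "binary_hull"))
  mask <- (agg$votes >= cfg$vote_cutoff) & hull$mask$data
  structure(list(mask = as_volume(mask, voxel_mm),
                 cochlea = NULL, vestibule = NULL),
            class = "els_mask")
}

#' Split an ELS mask into cochlear and vestibular compartments
#'
#' Intersects the ELS mask with compartment regions — either two disjoint
#' crop boxes (`list(cochlea = , vestibule = )`, each
#' `rbind(lo, hi)` voxel index ranges) or a compartment label array
#' (1 cochlea, 2 vestibule), e.g. the phantom ground truth upsampled to
#' the analysis grid. Voxels in neither region are dropped from the
#' compartment totals but kept in the whole-ear mask.
#'
#' @param els an `els_mask`.
#' @param regions crop boxes or an integer compartment array.
#' @return the `els_mask` with `cochlea` and `vestibule` masks filled in.
#' @export
split_compartments <- function(els, regions) {
  stopifnot(inherits(els, "els_mask"))
  d <- dim(els$mask$data)
  if (is.array(regions)) {
    stopifnot(identical(dim(regions), d))
    coch <- regions == 1L
    vest <- regions == 2L
  } else {
    box_mask <- function(b) {
      m <- array(FALSE, d)
      if (is.null(b)) return(m)
      m[b[1, 1]:b[2, 1], b[1, 2]:b[2, 2], b[1, 3]:b[2, 3]] <- TRUE
      m
    }
    coch <- box_mask(regions$cochlea)
    vest <- box_mask(regions$vestibule)
    if (any(coch & vest)) stop("cochlear and vestibular crop boxes overlap")
  }
  els$cochlea <- as_volume(els$mask$data & coch, els$mask$voxel_mm)
  els$vestibule <- as_volume(els$mask$data & vest, els$mask$voxel_mm)
  els
}

#' Run the full VOLT ensemble
#'
#' Convenience wrapper: classifications, aggregation and cut-off
#' classification in one call.
#'
#' @param fused fused Mi2 `volume` from [fuse()].
#' @param hull the `binary_hull`.
#' @param cfg a [volt_config()].
#' @return list with the `aggregation_volume` and the `els_mask`.
#' @export
run_volt <- function(fused, hull, cfg = volt_config()) {
  cls <- volt_classifications(fused, cfg)
  agg <- aggregate_votes(cls, n_expected = cfg$n_classifiers)
  list(aggregation = agg, els = classify_els(agg, cfg, hull))
}
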