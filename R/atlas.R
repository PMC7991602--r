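#' Build a side-independent probabilistic atlas from labyrinth masks
#'
#' The occupancy map is the mean of the binarised fluid masks, averaged
#' with its own left-right mirror so neither side is privileged.
#'
#' @param masks list of `labyrinth_mask` objects on one shared grid.
#' @return a `probabilistic_atlas`: `occupancy` (`volume`, values in
#'   `[0, 1]`) and `side_independent = TRUE`.
#' @export
build_atlas <- function(masks) {
  if (length(masks) < 1L) stop("at least one labyrinth mask is required")
  stopifnot(all(vapply(masks, inherits, logical(1), "labyrinth_mask")))
  d <- dim(masks[[1]]$label$data)
  occ <- array(0, dim = d)
  for (m in masks) {
    if (!identical(dim(m$label$data), d)) stop("atlas input masks must share a grid")
    occ <- occ + (m$label$data > 0L)
  }
  occ <- occ / length(masks)
  occ <- (occ + occ[, , d[3]:1, drop = FALSE]) / 2
  structure(
    list(occupancy = as_volume(occ, masks[[1]]$voxel_mm),
         side_independent = TRUE),
    class = "probabilistic_atlas"
  )
}

#' Affine transform parameters
#'
#' 12 degrees of freedom mapping atlas (moving) coordinates into subject
#' (fixed) coordinates, both expressed in mm relative to the respective
#' grid centres: `y = t + R(rx, ry, rz) S(scale) Sh(shear) x`. Rotations
#' are intrinsic x-y-z Euler angles in radians; shear terms are the
#' off-diagonal `(xy, xz, yz)` entries of an upper-triangular matrix.
#'
#' @param translation_mm,rotation_rad,scale,shear numeric 3-vectors.
#' @return an `affine_params` object.
#' @export
affine_params <- function(translation_mm = c(0, 0, 0),
                          rotation_rad = c(0, 0, 0),
                          scale = c(1, 1, 1),
                          shear = c(0, 0, 0)) {
  if (any(scale <= 0)) stop("scale parameters must be positive")
  structure(list(translation_mm = translation_mm,
                 rotation_rad = rotation_rad,
                 scale = scale, shear = shear),
            class = "affine_params")
}

affine_matrix <- function(p) {
  r <- p$rotation_rad
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  S <- diag(p$scale)
  Sh <- rbind(c(1, p$shear[1], p$shear[2]),
              c(0, 1, p$shear[3]),
              c(0, 0, 1))
  Rx %*% Ry %*% Rz %*% S %*% Sh
}

params_to_vec <- function(p) c(p$translation_mm, p$rotation_rad, p$scale, p$shear)
vec_to_params <- function(v) affine_params(v[1:3], v[4:6], v[7:9], v[10:12])

#' Registration configuration
#'
#' @param sampling_fraction fraction of candidate fixed-image voxels used
#'   for the similarity metric at each resolution level, in `(0, 1]`.
#' @param max_step_length optimiser translation step scale, voxels.
#' @param levels integer downsampling factors, coarse to fine.
#' @param max_iter optimiser iterations per level.
#' @param seed RNG seed for the voxel sampling.
#' @return a `registration_config` list.
#' @export
registration_config <- function(sampling_fraction = 0.5,
                                max_step_length = 0.5,
                                levels = c(4L, 2L),
                                max_iter = 40L,
                                seed = 1L) {
  stopifnot(sampling_fraction > 0, sampling_fraction <= 1, max_step_length > 0)
  structure(list(sampling_fraction = sampling_fraction,
                 max_step_length = max_step_length,
                 levels = as.integer(levels),
                 max_iter = as.integer(max_iter),
                 seed = as.integer(seed)),
            class = "registration_config")
}

# block-average downsample by an integer factor (truncating ragged edges)
downsample_volume <- function(v, f) {
  if (f == 1L) return(v)
  d <- dim(v$data) %/% f * f
  a <- v$data[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  dd <- d %/% f
  a <- array(a, dim = c(f, dd[1], f, dd[2], f, dd[3]))
  as_volume(apply(a, c(2, 4, 6), mean), v$voxel_mm * f)
}

# trilinear sampling of `arr` at continuous 1-based index coordinates
# (n x 3 matrix); points outside the grid return `outside`
sample_trilinear <- function(arr, pts, outside = 0) {
  d <- dim(arr)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(outside, nrow(pts))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  # direct linear indexing of the flattened array (hot path in registration)
  base <- x0 + (y0 - 1) * d[1] + (z0 - 1) * d[1] * d[2]
  s1 <- 1; s2 <- d[1]; s3 <- d[1] * d[2]
  v <- arr[base] * (1 - fx) * (1 - fy) * (1 - fz) +
    arr[base + s1] * fx * (1 - fy) * (1 - fz) +
    arr[base + s2] * (1 - fx) * fy * (1 - fz) +
    arr[base + s3] * (1 - fx) * (1 - fy) * fz +
    arr[base + s1 + s2] * fx * fy * (1 - fz) +
    arr[base + s1 + s3] * fx * (1 - fy) * fz +
    arr[base + s2 + s3] * (1 - fx) * fy * fz +
    arr[base + s1 + s2 + s3] * fx * fy * fz
  out[ok] <- v
  out
}

# mm coordinates (relative to grid centre) of 1-based indices and back
idx_to_mm <- function(idx, d, vox) sweep(sweep(idx, 2, (d + 1) / 2), 2, vox, `*`)
mm_to_idx <- function(mm, d, vox) sweep(sweep(mm, 2, vox, `/`), 2, (d + 1) / 2, `+`)

# resample the moving image onto the fixed grid under affine params
resample_moving <- function(moving, fixed_dim, fixed_vox, params) {
  A <- affine_matrix(params)
  Ainv <- solve(A)
  idx <- as.matrix(expand.grid(x = seq_len(fixed_dim[1]),
                               y = seq_len(fixed_dim[2]),
                               z = seq_len(fixed_dim[3])))
  y_mm <- idx_to_mm(idx, fixed_dim, fixed_vox)
  x_mm <- sweep(y_mm, 2, params$translation_mm) %*% t(Ainv)
  x_idx <- mm_to_idx(x_mm, dim(moving$data), moving$voxel_mm)
  array(sample_trilinear(moving$data, x_idx), dim = fixed_dim)
}

#' Apply an affine transform to a volume
#'
#' Resamples `moving` onto the grid of `fixed` under `params` (trilinear
#' interpolation, zero outside the moving field of view).
#'
#' @param moving,fixed `volume`s.
#' @param params [affine_params()].
#' @return a `volume` on the fixed grid.
#' @export
transform_volume <- function(moving, fixed, params) {
  stopifnot(is_volume(moving), is_volume(fixed))
  as_volume(resample_moving(moving, dim(fixed$data), fixed$voxel_mm, params),
            fixed$voxel_mm)
}

#' Register the probabilistic atlas to a subject MRC volume
#'
#' Multiresolution affine registration minimising the mean-squared intensity
#' difference between the (intensity-normalised) fixed MRC and the
#' transformed atlas occupancy over a random subset of fixed-image voxels
#' (fraction per level from the config, seeded so runs are deterministic).
#' The coarsest level is preceded by an exhaustive translation search so
#' the optimiser starts inside the capture range.
#'
#' @param atlas a `probabilistic_atlas`.
#' @param mrc the subject's preprocessed MRC `volume` (fixed image).
#' @param cfg a [registration_config()].
#' @param init optional initial [affine_params()].
#' @return [affine_params()] with attributes `metric` (final MSE) and
#'   `converged`.
#' @export
register_affine <- function(atlas, mrc, cfg = registration_config(),
                            init = affine_params()) {
  stopifnot(inherits(atlas, "probabilistic_atlas"), is_volume(mrc))
  fixed_full <- as_volume(normalise01(mrc$data), mrc$voxel_mm)
  moving_full <- atlas$occupancy
  vec <- params_to_vec(init)
  levels <- sort(unique(cfg$levels), decreasing = TRUE)
  for (li in seq_along(levels)) {
    f <- levels[li]
    fixed <- downsample_volume(fixed_full, f)
    # downsample the moving image only as far as needed to match the
    # fixed level's resolution (edge-profile widths must be comparable,
    # or the scale estimate biases outward)
    mov_f <- max(1L, round(f * fixed_full$voxel_mm[1] / moving_full$voxel_mm[1]))
    moving <- downsample_volume(moving_full, mov_f)
    d <- dim(fixed$data)
    # candidates: union of fixed-image signal and the moving image's
    # support under the current estimate, slightly dilated — so both
    # missing coverage and overhang of the atlas are penalised
    mov_here <- resample_moving(moving, d, fixed$voxel_mm, vec_to_params(vec))
    cand <- which(dilate_mask(fixed$data > 0.05 | mov_here > 0.05, 2L))
    n_s <- max(20L, round(cfg$sampling_fraction * length(cand)))
    samp <- withr::with_seed(
      substream_seed(cfg$seed, paste0("regsample-", f)),
      sort(sample(cand, min(n_s, length(cand), 15000L)))
    )
    idx <- arrayInd(samp, d)
    y_mm <- idx_to_mm(idx, d, fixed$voxel_mm)
    fvals <- fixed$data[samp]
    mdim <- dim(moving$data)
    objective <- function(v) {
      p <- tryCatch(vec_to_params(v), error = function(e) NULL)
      if (is.null(p)) return(1e6)
      Ainv <- tryCatch(solve(affine_matrix(p)), error = function(e) NULL)
      if (is.null(Ainv)) return(1e6)
      x_mm <- sweep(y_mm, 2, p$translation_mm) %*% t(Ainv)
      x_idx <- mm_to_idx(x_mm, mdim, moving$voxel_mm)
      mean((fvals - sample_trilinear(moving$data, x_idx))^2)
    }
    if (li == 1L) {
      # capture-range translation search on the coarsest grid
      step <- fixed$voxel_mm[1]
      offs <- as.matrix(expand.grid(tx = -3:3 * step, ty = -3:3 * step,
                                    tz = -3:3 * step))
      best <- vec
      best_val <- objective(vec)
      for (i in seq_len(nrow(offs))) {
        v2 <- vec
        v2[1:3] <- vec[1:3] + offs[i, ]
        val <- objective(v2)
        if (val < best_val) { best_val <- val; best <- v2 }
      }
      vec <- best
    }
    parscale <- c(rep(cfg$max_step_length * fixed$voxel_mm[1], 3),
                  rep(0.02, 3), rep(0.02, 3), rep(0.02, 3))
    # stage 1: translation only (well-conditioned), stage 2: all 12 DOF
    obj_t <- function(t3) { v <- vec; v[1:3] <- t3; objective(v) }
    opt_t <- stats::optim(vec[1:3], obj_t, method = "BFGS",
                          control = list(maxit = cfg$max_iter,
                                         parscale = parscale[1:3],
                                         reltol = 1e-10))
    vec[1:3] <- opt_t$par
    opt <- stats::optim(vec, objective, method = "BFGS",
                        control = list(maxit = cfg$max_iter,
                                       parscale = parscale,
                                       reltol = 1e-10))
    vec <- opt$par
    # final translation polish: re-centres the solution with the other
    # 9 parameters frozen (translation is what downstream masking feels)
    opt_t2 <- stats::optim(vec[1:3], obj_t, method = "BFGS",
                           control = list(maxit = cfg$max_iter,
                                          parscale = parscale[1:3],
                                          reltol = 1e-10))
    vec[1:3] <- opt_t2$par
  }
  out <- vec_to_params(vec)
  attr(out, "metric") <- opt$value
  attr(out, "converged") <- opt$convergence == 0
  out
}

normalise01 <- function(a) {
  lo <- min(a); hi <- max(a)
  if (hi <= lo) return(array(0, dim(a)))
  (a - lo) / (hi - lo)
}

#' Binarise a registered atlas into a subject-space ROI mask
#'
#' @param atlas a `probabilistic_atlas`.
#' @param mrc fixed-grid `volume` defining the output grid.
#' @param params [affine_params()] from [register_affine()].
#' @param threshold occupancy threshold (default 0.5).
#' @return logical array on the MRC grid.
#' @export
atlas_roi <- function(atlas, mrc, params = affine_params(), threshold = 0.5) {
  occ <- transform_volume(atlas$occupancy, mrc, params)
  occ$data >= threshold
}

#' Extract the total-fluid-space binary hull from an MRC volume
#'
#' Within (a dilation of) the registered atlas ROI the MRC histogram is
#' thresholded by Otsu's method; the largest connected component on each
#' side of the left-right midplane is kept and internal holes are filled.
#' The result is the binary hull of the total fluid space (TFS).
#'
#' @param mrc preprocessed MRC `volume`.
#' @param roi logical array (registered, binarised atlas) on the MRC grid.
#' @param roi_dilate_voxels dilation applied to the ROI before thresholding.
#' @return a `binary_hull`: `mask` (`volume`, logical), `voxel_count`,
#'   `volume_mm3`, `otsu_threshold`.
#' @export
extract_hull <- function(mrc, roi, roi_dilate_voxels = 2L) {
  stopifnot(is_volume(mrc), identical(dim(roi), dim(mrc$data)))
  roi_d <- dilate_mask(roi, roi_dilate_voxels)
  vals <- mrc$data[roi_d]
  if (length(vals) == 0L || max(vals) <= min(vals)) {
    stop("no fluid signal in ROI")
  }
  thr <- EBImage::otsu(EBImage::Image(matrix(vals / 255, ncol = 1)),
                       range = c(0, 1), levels = 256L) * 255
  fg <- array(FALSE, dim(mrc$data))
  fg[roi_d] <- mrc$data[roi_d] > thr
  if (!any(fg)) stop("no fluid signal in ROI")
  cc <- label_components(fg)
  mid <- (dim(fg)[3] + 1) / 2
  keep <- integer(0)
  for (half in c("left", "right")) {
    ids <- which(vapply(seq_along(cc$sizes), function(i) {
      zc <- mean(arrayInd(which(cc$labels == i), dim(fg))[, 3])
      if (half == "left") zc < mid else zc >= mid
    }, logical(1)))
    if (length(ids)) keep <- c(keep, ids[which.max(cc$sizes[ids])])
  }
  mask <- array(cc$labels %in% keep, dim = dim(fg))
  mask <- fill_holes(mask)
  new_hull(mask, mrc$voxel_mm, otsu = thr)
}

new_hull <- function(mask, voxel_mm, otsu = NA_real_) {
  structure(list(mask = as_volume(mask, voxel_mm),
                 voxel_count = sum(mask),
                 volume_mm3 = sum(mask) * prod(voxel_mm),
                 otsu_threshold = otsu),
            class = "binary_hull")
}

#' @export
print.binary_hull <- function(x, ...) {
  cat(sprintf("<binary_hull> %d voxels, %.2f mm^3\n", x$voxel_count, x$volume_mm3))
  invisible(x)
}

#' Morphological dilation of a binary hull
#'
#' Discrete ball (6-connectivity cross per unit radius) structuring
#' element; monotone in the radius.
#'
#' @param h a `binary_hull`.
#' @param radius_voxels integer radius >= 0.
#' @return the dilated `binary_hull`.
#' @export
dilate_hull <- function(h, radius_voxels = 1L) {
  stopifnot(inherits(h, "binary_hull"), radius_voxels >= 0)
  new_hull(dilate_mask(h$mask$data, radius_voxels), h$mask$voxel_mm,
           otsu = h$otsu_threshold)
}

#' Fuse the Mi2 volume with the (dilated) binary hull
#'
#' Keeps Mi2 intensities inside the hull and sets voxels outside to `NA`,
#' the sentinel that excludes them from all window statistics and vote
#' counts downstream.
#'
#' @param h a `binary_hull` (typically dilated by one voxel).
#' @param mi2 the preprocessed HYDROPS-Mi2 `volume` on the same grid.
#' @return a `volume` with `NA` outside the hull.
#' @export
fuse <- function(h, mi2) {
  stopifnot(inherits(h, "binary_hull"))
  check_same_grid(h$mask, mi2, c("hull", "Mi2"))
  if (h$voxel_count == 0L) stop("hull is empty; nothing to fuse")
  a <- mi2$data
  a[!h$mask$data] <- NA_real_
  as_volume(a, mi2$voxel_mm)
}
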