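#' Preprocessing configuration
#'
#' Parameters of the image-preparation chain applied before segmentation:
#' cropping a cuboid around the inner ears, 8-bit conversion, integer-factor
#' rescaling with quintic B-spline interpolation, and histogram-based noise
#' reduction of the MRC volume.
#'
#' @param crop_size_mm physical crop extent per axis, mm (default
#'   `c(30, 30, 52)` — the cuboid that holds both inner ears).
#' @param rescale_factor integer upsampling factor (default 2).
#' @param denoise_percentiles low/high clip percentiles for the MRC
#'   histogram noise reduction. The fluid space occupies well under 1% of
#'   the cropped cuboid, so the high percentile must stay above the start
#'   of the fluid intensity class: the default (0.5, 99.99) clips only
#'   extreme outliers at the top while flattening the background's low
#'   tail.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(crop_size_mm = c(30, 30, 52),
                              rescale_factor = 2L,
                              denoise_percentiles = c(0.5, 99.99)) {
  stopifnot(length(crop_size_mm) == 3, all(crop_size_mm > 0),
            rescale_factor >= 1)
  p <- denoise_percentiles
  if (length(p) != 2 || p[1] < 0 || p[2] > 100 || p[1] >= p[2]) {
    stop("denoise_percentiles must satisfy 0 <= low < high <= 100")
  }
  structure(list(crop_size_mm = crop_size_mm,
                 rescale_factor = as.integer(rescale_factor),
                 denoise_percentiles = p),
            class = "preprocess_config")
}

#' HYDROPS subtraction image
#'
#' Voxelwise PPI minus PEI on a shared grid. Perilymph (bright on PPI, dark
#' on PEI) comes out positive, endolymph negative; values stay signed — no
#' clipping happens at this stage.
#'
#' @param ppi,pei `volume`s on identical grids.
#' @return a signed `volume`.
#' @export
compute_hydrops <- function(ppi, pei) {
  check_same_grid(ppi, pei, c("PPI", "PEI"))
  as_volume(ppi$data - pei$data, ppi$voxel_mm)
}

#' HYDROPS-Mi2 image
#'
#' Voxelwise product of the HYDROPS subtraction image with the MRC
#' cisternography volume. MRC is near zero outside fluid, so the product
#' suppresses background toward zero and boosts the contrast-to-noise of
#' the fluid signal.
#'
#' @param hydrops signed HYDROPS `volume`.
#' @param mrc MRC `volume` on the same grid.
#' @return a signed `volume`.
#' @export
compute_mi2 <- function(hydrops, mrc) {
  check_same_grid(hydrops, mrc, c("HYDROPS", "MRC"))
  as_volume(hydrops$data * mrc$data, hydrops$voxel_mm)
}

#' Crop a physical cuboid from a volume
#'
#' Extracts a cuboid of extent `cfg$crop_size_mm` centred at `center_mm`
#' (mm offsets from the grid centre). The output extent matches the
#' requested size to within one voxel per axis; voxel size is unchanged.
#'
#' @param v a `volume`.
#' @param center_mm 3-vector, mm offsets of the cuboid centre from the grid
#'   centre.
#' @param cfg a [preprocess_config()].
#' @return the cropped `volume`.
#' @export
crop_cuboid <- function(v, center_mm = c(0, 0, 0), cfg = preprocess_config()) {
  stopifnot(is_volume(v))
  d <- dim(v$data)
  idx <- vector("list", 3)
  for (ax in 1:3) {
    n_out <- round(cfg$crop_size_mm[ax] / v$voxel_mm[ax])
    centre_idx <- (d[ax] + 1) / 2 + center_mm[ax] / v$voxel_mm[ax]
    i0 <- round(centre_idx - (n_out + 1) / 2)
    if (i0 < 0 || i0 + n_out > d[ax]) {
      lo <- max(0, min(i0, d[ax] - n_out))
      stop(sprintf(
        "crop cuboid out of bounds along axis %d (start %d, length %d, extent %d); nearest feasible centre offset: %.2f mm",
        ax, i0 + 1, n_out, d[ax],
        ((lo + (n_out + 1) / 2) - (d[ax] + 1) / 2) * v$voxel_mm[ax]
      ))
    }
    idx[[ax]] <- i0 + seq_len(n_out)
  }
  as_volume(v$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE], v$voxel_mm)
}

#' Linear 8-bit conversion
#'
#' Maps `[min, max]` linearly onto `[0, 255]`, rounding half-to-even. A
#' constant volume maps to 0 rather than mid-grey, so no contrast is
#' invented where none exists.
#'
#' @param v a `volume` with finite values.
#' @return an 8-bit `volume` (integer-valued doubles in 0..255).
#' @export
to_8bit <- function(v) {
  stopifnot(is_volume(v), all(is.finite(v$data)))
  lo <- min(v$data); hi <- max(v$data)
  if (hi <= lo) return(as_volume(array(0, dim(v$data)), v$voxel_mm))
  as_volume(round((v$data - lo) / (hi - lo) * 255), v$voxel_mm)
}

#' Histogram-based noise reduction
#'
#' Clips intensities at the configured low/high percentiles and re-stretches
#' the clipped range to the full 8-bit scale. Applied to the MRC volume to
#' flatten background speckle before atlas registration and thresholding.
#' A volume with no spread between the two percentiles is returned
#' unchanged.
#'
#' @param v a `volume` (8-bit scale).
#' @param cfg a [preprocess_config()].
#' @return the denoised `volume`.
#' @export
denoise_histogram <- function(v, cfg = preprocess_config()) {
  stopifnot(is_volume(v))
  q <- stats::quantile(v$data, probs = cfg$denoise_percentiles / 100,
                       names = FALSE, type = 7)
  if (q[2] <= q[1]) return(v)
  x <- pmin(pmax(v$data, q[1]), q[2])
  as_volume(round((x - q[1]) / (q[2] - q[1]) * 255), v$voxel_mm)
}

#' Run the full preprocessing chain on a sequence triplet
#'
#' HYDROPS (PPI - PEI) and HYDROPS-Mi2 (HYDROPS x MRC) are built at
#' acquisition resolution; MRC and Mi2 are then cropped to the inner-ear
#' cuboid, converted to 8 bits, rescaled, and the MRC is
#' histogram-denoised. The signed Mi2 volume is quantised only at the
#' 8-bit step, after the multiplication.
#'
#' @param triplet list with `volume`s `mrc`, `ppi`, `pei` on one grid.
#' @param cfg a [preprocess_config()].
#' @param center_mm crop centre, mm offsets from the grid centre.
#' @return list with processed `mrc`, `mi2` volumes and the applied
#'   parameters.
#' @export
preprocess_subject <- function(triplet, cfg = preprocess_config(),
                               center_mm = c(0, 0, 0)) {
  hyd <- compute_hydrops(triplet$ppi, triplet$pei)
  mi2 <- compute_mi2(hyd, triplet$mrc)
  mrc_c <- crop_cuboid(triplet$mrc, center_mm, cfg)
  mi2_c <- crop_cuboid(mi2, center_mm, cfg)
  mrc_p <- rescale_volume(to_8bit(mrc_c), cfg$rescale_factor)
  mi2_p <- rescale_volume(to_8bit(mi2_c), cfg$rescale_factor)
  mrc_p <- denoise_histogram(mrc_p, cfg)
  list(mrc = mrc_p, mi2 = mi2_p,
       params = list(crop_size_mm = cfg$crop_size_mm,
                     rescale_factor = cfg$rescale_factor,
                     denoise_percentiles = cfg$denoise_percentiles,
                     crop_center_mm = center_mm))
}
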