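#' Lightweight 3D image volume
#'
#' A `volume` is a 3D numeric array with an isotropic-or-not voxel size in
#' millimetres. It is the carrier for all image types in the pipeline:
#' MRC (heavily T2-weighted cisternography), PPI/PEI (positive
#' perilymph/endolymph FLAIR), the HYDROPS subtraction image, the
#' HYDROPS-Mi2 product image, vote aggregations and binary masks.
#' Axis convention: index order (x, y, z) where axis 1 is
#' anterior-posterior, axis 2 inferior-superior ("axial" slices are fixed
#' axis-2 planes, low index = inferior) and axis 3 left-right.
#'
#' @param data 3D numeric array.
#' @param voxel_mm voxel edge length in mm, length 1 (isotropic) or 3.
#' @return A `volume` object.
#' @export
as_volume <- function(data, voxel_mm) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  if (length(voxel_mm) != 3L || any(!is.finite(voxel_mm)) || any(voxel_mm <= 0)) {
    stop("`voxel_mm` must be 1 or 3 positive numbers")
  }
  structure(list(data = data, voxel_mm = voxel_mm), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm  [%.4g, %.4g]\n",
    d[1], d[2], d[3], x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3],
    min(x$data, na.rm = TRUE), max(x$data, na.rm = TRUE)
  ))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

#' Voxel volume in cubic millimetres
#' @param v a `volume` or a `labyrinth_mask`.
#' @return scalar, mm^3 per voxel.
#' @export
voxel_volume_mm3 <- function(v) prod(v$voxel_mm)

is_volume <- function(x) inherits(x, "volume")

#' Check that two volumes share a grid
#'
#' Errors naming the differing attribute (shape or voxel size); used as the
#' precondition of every voxelwise operation.
#'
#' @param a,b `volume` objects.
#' @param what names used in the error message.
#' @return invisibly `TRUE`.
#' @export
check_same_grid <- function(a, b, what = c("first", "second")) {
  stopifnot(is_volume(a), is_volume(b))
  if (!identical(dim(a$data), dim(b$data))) {
    stop(sprintf(
      "grid mismatch between %s and %s volumes: shape %s vs %s",
      what[1], what[2], paste(dim(a$data), collapse = "x"),
      paste(dim(b$data), collapse = "x")
    ))
  }
  if (!isTRUE(all.equal(a$voxel_mm, b$voxel_mm, tolerance = 1e-8))) {
    stop(sprintf(
      "grid mismatch between %s and %s volumes: voxel size %s vs %s mm",
      what[1], what[2], paste(signif(a$voxel_mm, 6), collapse = "x"),
      paste(signif(b$voxel_mm, 6), collapse = "x")
    ))
  }
  invisible(TRUE)
}

#' Read / write a volume as NIfTI-1
#'
#' Thin wrappers over \pkg{RNifti}; the voxel size is carried in the NIfTI
#' header (`pixdim`).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` a `volume`; `write_volume()` the path, invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  as_volume(array(as.numeric(img), dim = dim(img)), RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @param v a `volume`.
#' @export
write_volume <- function(v, path) {
  stopifnot(is_volume(v))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Nearest-neighbour upsampling of a label volume
#'
#' Replicates each voxel `factor` times along every axis; used to compare
#' ground-truth labels (built at acquisition resolution) with masks on the
#' rescaled analysis grid.
#'
#' @param v a `volume` (any numeric/integer labels).
#' @param factor positive integer.
#' @return a `volume` on the finer grid.
#' @export
upsample_labels <- function(v, factor = 2L) {
  stopifnot(is_volume(v), factor >= 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(v)
  d <- dim(v$data)
  idx <- function(n) rep(seq_len(n), each = factor)
  as_volume(v$data[idx(d[1]), idx(d[2]), idx(d[3]), drop = FALSE],
            v$voxel_mm / factor)
}

#' Extract an axial slice as a tibble (long form) for plotting
#'
#' @param v a `volume`.
#' @param slice index along axis 2 (inferior-superior).
#' @return tibble with columns `x`, `z`, `value`.
#' @export
slice_tbl <- function(v, slice) {
  stopifnot(is_volume(v))
  m <- v$data[, slice, ]
  tibble::tibble(
    x = rep(seq_len(nrow(m)), times = ncol(m)),
    z = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

#' Plot an axial slice of a volume
#'
#' @param v a `volume`.
#' @param slice axial slice index (default: middle slice).
#' @return a ggplot object.
#' @export
plot_slice <- function(v, slice = NULL) {
  if (is.null(slice)) slice <- ceiling(dim(v$data)[2] / 2)
  df <- slice_tbl(v, slice)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("axial slice %d", slice),
      x = "anterior-posterior [voxel]", y = "left-right [voxel]", fill = "intensity"
    )
}

# shift an array by k voxels along an axis, zero-filling; workhorse for the
# vectorised 3D morphology below
shift_array <- function(a, axis, k) {
  if (k == 0L) return(a)
  d <- dim(a)
  out <- array(vector(typeof(a), 1L), dim = d)
  src <- dst <- lapply(d, seq_len)
  n <- d[axis]
  if (abs(k) >= n) return(out)
  if (k > 0) { dst[[axis]] <- (k + 1L):n; src[[axis]] <- 1L:(n - k) }
  else { dst[[axis]] <- 1L:(n + k); src[[axis]] <- (1L - k):n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# one 6-connected binary dilation step
dilate_step <- function(m) {
  out <- m
  for (ax in 1:3) {
    out <- out | shift_array(m, ax, 1L) | shift_array(m, ax, -1L)
  }
  out
}

# binary dilation with a discrete 6-connectivity ball of given radius
# (radius 1 turns a single voxel into the 7-voxel cross)
dilate_mask <- function(m, radius) {
  radius <- as.integer(radius)
  stopifnot(radius >= 0)
  for (i in seq_len(radius)) m <- dilate_step(m)
  m
}

# fill internal holes: flood the background from the array border (iterated
# 6-connected propagation constrained to background), then everything not
# reached and not foreground is a hole
fill_holes <- function(m) {
  # work inside the mask's bounding box (plus one border layer of certain
  # background) so the flood fill does not crawl across the whole grid
  idx <- which(m)
  if (length(idx) == 0L) return(m)
  pos <- arrayInd(idx, dim(m))
  lo <- pmax(apply(pos, 2, min) - 1L, 1L)
  hi <- pmin(apply(pos, 2, max) + 1L, dim(m))
  sub <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- fill_holes_dense(sub)
  m
}

fill_holes_dense <- function(m) {
  bg <- !m
  reach <- array(FALSE, dim = dim(m))
  # seed: all border voxels that are background
  d <- dim(m)
  reach[c(1, d[1]), , ] <- bg[c(1, d[1]), , ]
  reach[, c(1, d[2]), ] <- reach[, c(1, d[2]), ] | bg[, c(1, d[2]), ]
  reach[, , c(1, d[3])] <- reach[, , c(1, d[3])] | bg[, , c(1, d[3])]
  repeat {
    grown <- dilate_step(reach) & bg
    if (!any(grown & !reach)) break
    reach <- reach | grown
  }
  m | (bg & !reach)
}

# label 6-connected components of a binary 3D mask via igraph; returns an
# integer array (0 = background) and component sizes
label_components <- function(m) {
  idx <- which(m)
  lab <- array(0L, dim = dim(m))
  if (length(idx) == 0L) return(list(labels = lab, sizes = integer(0)))
  d <- dim(m)
  pos <- arrayInd(idx, d)
  key <- array(0L, dim = d)
  key[idx] <- seq_along(idx)
  edges <- integer(0)
  for (ax in 1:3) {
    nb <- pos
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= d[ax]
    nb_key <- key[nb[ok, , drop = FALSE]]
    here <- seq_along(idx)[ok]
    has <- nb_key > 0L
    edges <- c(edges, rbind(here[has], nb_key[has]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  lab[idx] <- comp$membership
  list(labels = lab, sizes = as.integer(comp$csize))
}
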