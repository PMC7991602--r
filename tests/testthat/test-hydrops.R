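test_that("HYDROPS subtraction: zero, antisymmetry, grid mismatch", {
  a <- as_volume(array(runif(60, 0, 255), c(3, 4, 5)), 0.5)
  b <- as_volume(array(runif(60, 0, 255), c(3, 4, 5)), 0.5)
  expect_true(all(compute_hydrops(a, a)$data == 0))
  expect_equal(compute_hydrops(b, a)$data, -compute_hydrops(a, b)$data)
  bad <- as_volume(array(0, c(3, 4, 6)), 0.5)
  expect_error(compute_hydrops(a, bad), "PPI.*PEI")
})

test_that("HYDROPS polarity is exact on the noise-free phantom", {
  sp <- small_spec(0.3, 0.3, noise = 0)
  m <- build_labyrinth(sp)
  tr <- simulate_sequences(m, sp)
  hyd <- compute_hydrops(tr$ppi, tr$pei)
  expect_true(all(hyd$data[m$label$data == 2L] < 0))
  expect_true(all(hyd$data[m$label$data == 1L] > 0))
  # Mi2 keeps the sign inside fluid (MRC > 0 there)
  mi2 <- compute_mi2(hyd, tr$mrc)
  fluid <- m$label$data > 0L
  expect_equal(sign(mi2$data[fluid]), sign(hyd$data[fluid]))
})

test_that("Mi2 multiplication: zeros and identity", {
  h <- as_volume(array(rnorm(24), c(2, 3, 4)), 1)
  zero <- as_volume(array(0, c(2, 3, 4)), 1)
  one <- as_volume(array(1, c(2, 3, 4)), 1)
  expect_true(all(compute_mi2(h, zero)$data == 0))
  expect_equal(compute_mi2(h, one)$data, h$data)
})

test_that("cuboid crop: voxel counts, identity, idempotence, bounds", {
  v <- as_volume(array(rnorm(68 * 68 * 112), c(68, 68, 112)), 0.5)
  cfg <- preprocess_config(crop_size_mm = c(30, 30, 52))
  cv <- crop_cuboid(v, c(0, 0, 0), cfg)
  expect_equal(dim(cv$data), c(60L, 60L, 104L))
  expect_equal(cv$voxel_mm, rep(0.5, 3))
  # crop equal to full extent is the identity
  full <- preprocess_config(crop_size_mm = c(34, 34, 56))
  expect_equal(crop_cuboid(v, c(0, 0, 0), full)$data, v$data)
  # idempotent
  expect_equal(crop_cuboid(cv, c(0, 0, 0), cfg)$data, cv$data)
  # out of bounds errors with a suggestion
  expect_error(crop_cuboid(v, c(30, 0, 0), cfg), "axis 1.*centre offset")
})

test_that("8-bit conversion: degenerate input, endpoints, monotonicity", {
  const <- as_volume(array(42, c(2, 2, 2)), 1)
  expect_true(all(to_8bit(const)$data == 0))
  two <- as_volume(array(c(0, 510), c(2, 1, 1)), 1)
  expect_equal(as.vector(to_8bit(two)$data), c(0, 255))
  x <- as_volume(array(sort(rnorm(27)), c(3, 3, 3)), 1)
  y <- to_8bit(x)$data
  expect_true(all(diff(as.vector(y)) >= 0))
  expect_true(min(y) == 0 && max(y) == 255)
})

test_that("quintic B-spline rescale: identity, shape, constants", {
  set.seed(3)
  v <- as_volume(array(rnorm(16 * 14 * 12), c(16, 14, 12)), 0.5)
  r1 <- rescale_volume(v, 1L)
  expect_lt(max(abs(r1$data - v$data)), 1e-6)
  r2 <- rescale_volume(v, 2L)
  expect_equal(dim(r2$data), c(32L, 28L, 24L))
  expect_equal(r2$voxel_mm, rep(0.25, 3))
  const <- as_volume(array(7, c(6, 6, 6)), 0.5)
  expect_lt(max(abs(rescale_volume(const, 2L)$data - 7)), 1e-9)
})

test_that("histogram denoise: identity, outlier clipping, constants", {
  # already-stretched volume with full percentile range is unchanged
  v <- as_volume(array(round(seq(0, 255, length.out = 64)), c(4, 4, 4)), 1)
  cfg_full <- preprocess_config(denoise_percentiles = c(0, 100))
  expect_equal(denoise_histogram(v, cfg_full)$data, v$data)
  # a single bright outlier is clipped at the 99th percentile: the output
  # maximum is then attained by ordinary voxels too
  a <- array(100, c(5, 5, 8))
  a[1, 1, 1] <- 255
  a[5, 5, 8] <- 0
  w <- as_volume(a, 1)
  q99 <- as.numeric(stats::quantile(a, 0.99))
  expect_lt(q99, 255)  # the oracle: the outlier sits above the clip level
  out <- denoise_histogram(w, preprocess_config(denoise_percentiles = c(0, 99)))
  expect_gt(sum(out$data == max(out$data)), 1L)
  const <- as_volume(array(9, c(3, 3, 3)), 1)
  expect_equal(denoise_histogram(const)$data, const$data)
  expect_error(preprocess_config(denoise_percentiles = c(50, 40)))
})

test_that("preprocessing preserves grid metadata consistently", {
  sp <- small_spec(0.3, 0.3, noise = 0)
  subj <- make_phantom_subject(sp)
  cfg <- preprocess_config(crop_size_mm = c(20, 20, 38))
  pre <- preprocess_subject(subj$triplet, cfg)
  expect_equal(dim(pre$mrc$data), dim(pre$mi2$data))
  expect_equal(pre$mrc$voxel_mm, rep(0.25, 3))
  # physical extent preserved within one voxel per axis
  expect_equal(dim(pre$mrc$data) * pre$mrc$voxel_mm, c(20, 20, 38),
               tolerance = 0.26)
})
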