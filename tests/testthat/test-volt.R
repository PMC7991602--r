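test_that("constant slices produce no votes (strict tie rule)", {
  fused <- as_volume(array(100, c(16, 16, 1)), 1)
  v <- local_threshold_slicewise(fused, 3, "mean", 6, offset = 0)
  expect_false(any(v))
})

test_that("a dark patch on a bright field votes exactly (window-mean oracle)", {
  sl <- matrix(200, 16, 16)
  sl[7:9, 7:9] <- 40
  fused <- as_volume(array(sl, c(16, 16, 1)), 1)
  got <- local_threshold_slicewise(fused, 3, "mean", 6, offset = 0)[, , 1]
  # brute-force window means on the constructed array
  expected <- matrix(FALSE, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    ii <- max(1, i - 6):min(16, i + 6); jj <- max(1, j - 6):min(16, j + 6)
    expected[i, j] <- sl[i, j] < mean(sl[ii, jj])
  }
  expect_identical(got, expected)
  expect_equal(sum(got[7:9, 7:9]), 9L)        # all patch voxels vote
  expect_equal(sum(got) , 9L)                 # and only those
})

test_that("Niblack with k = 0 equals the local mean with offset 0", {
  set.seed(5)
  fused <- as_volume(array(sample(0:255, 16 * 16 * 4, TRUE), c(16, 16, 4)), 1)
  for (ax in 1:3) {
    nb <- local_threshold_slicewise(fused, ax, "niblack", 4, k = 0)
    mn <- local_threshold_slicewise(fused, ax, "mean", 4, offset = 0)
    expect_identical(nb, mn)
  }
})

test_that("sentinel voxels never vote and are excluded from window statistics", {
  sl <- matrix(200, 12, 12)
  sl[6, 6] <- 40
  sl[1:3, 1:3] <- NA           # outside hull
  fused <- as_volume(array(sl, c(12, 12, 1)), 1)
  v <- local_threshold_slicewise(fused, 3, "mean", 5)[, , 1]
  expect_false(any(v[1:3, 1:3]))
  expect_true(v[6, 6])
  # window statistics ignore the NAs: identical decision to an array where
  # the masked corner simply does not exist in the window sums
  expect_equal(sum(v), 1L)
})

test_that("aggregation sums votes and validates inputs", {
  d <- c(6, 6, 2)
  zeros <- replicate(12, array(FALSE, d), simplify = FALSE)
  ones <- replicate(12, array(TRUE, d), simplify = FALSE)
  expect_true(all(aggregate_votes(zeros)$votes == 0L))
  expect_true(all(aggregate_votes(ones)$votes == 12L))
  set.seed(2)
  rnd <- replicate(12, array(runif(prod(d)) > 0.5, d), simplify = FALSE)
  a1 <- aggregate_votes(rnd)$votes
  a2 <- aggregate_votes(rev(rnd))$votes
  expect_identical(a1, a2)                    # order invariance
  expect_error(aggregate_votes(rnd[1:11]), "expected 12")
  bad <- rnd; bad[[3]] <- array(FALSE, c(6, 6, 3))
  expect_error(aggregate_votes(bad), "grids differ")
})

test_that("cut-off classification is strict and monotone", {
  d <- c(4, 4, 4)
  votes <- array(11L, d)
  agg <- structure(list(votes = votes, provenance = NULL),
                   class = "aggregation_volume")
  hull <- hydroquant:::new_hull(array(TRUE, d), rep(1, 3))
  m12 <- classify_els(agg, volt_config(vote_cutoff = 12L), hull)
  expect_false(any(m12$mask$data))            # 11 votes < cutoff 12
  m1 <- classify_els(agg, volt_config(vote_cutoff = 1L), hull)
  expect_identical(m1$mask$data, hull$mask$data)
  # lowering the cutoff never shrinks the mask
  set.seed(9)
  agg$votes <- array(sample(0:12, prod(d), TRUE), d)
  prev <- NULL
  for (k in 12:1) {
    mk <- classify_els(agg, volt_config(vote_cutoff = k), hull)$mask$data
    if (!is.null(prev)) expect_true(all(!prev | mk))
    prev <- mk
  }
  expect_error(volt_config(vote_cutoff = 13L), "must lie in")
})

test_that("full ensemble equals the brute-force window-statistic oracle", {
  set.seed(101)
  for (rep in 1:3) {
    vals <- array(sample(0:255, 16 * 16 * 8, TRUE), c(16, 16, 8))
    hull <- array(runif(16 * 16 * 8) > 0.15, c(16, 16, 8))
    fused_arr <- vals
    fused_arr[!hull] <- NA_real_
    fused <- as_volume(fused_arr, 1)
    agg <- aggregate_votes(hydroquant:::volt_classifications(fused, volt_config()))
    oracle <- brute_volt_votes(vals, hull)
    expect_identical(agg$votes, oracle)
  }
})

test_that("votes are consistent under 90-degree grid rotations", {
  set.seed(11)
  vals <- array(sample(0:255, 12 * 12 * 12, TRUE), c(12, 12, 12))
  hull <- array(runif(12^3) > 0.2, c(12, 12, 12))
  fa <- vals; fa[!hull] <- NA_real_
  fused <- as_volume(fa, 1)
  base <- aggregate_votes(hydroquant:::volt_classifications(fused, volt_config(window_radii = c(2L, 4L))))
  for (ax in 1:3) {
    rot <- as_volume(rot90_about(fa, ax), 1)
    va <- aggregate_votes(hydroquant:::volt_classifications(rot, volt_config(window_radii = c(2L, 4L))))
    expect_identical(unrot90_about(va$votes, ax), base$votes,
                     label = sprintf("rotation about axis %d", ax))
  }
})

test_that("compartment splitting partitions and validates boxes", {
  run <- small_run()
  els <- run$result$els
  comp <- run$result$truth_analysis$compartment$data
  # compartment ELS counts sum to at most the whole-ear count, and voxels in
  # neither region are kept in the whole mask
  n_c <- sum(els$cochlea$data); n_v <- sum(els$vestibule$data)
  expect_lte(n_c + n_v, sum(els$mask$data))
  expect_false(any(els$cochlea$data & els$vestibule$data))
  # vestibular mask never intersects the true cochlea
  expect_equal(sum(els$vestibule$data & comp == 1L), 0L)
  # boxes: empty cochlear box leaves no cochlear ELS; overlap errors
  d <- dim(els$mask$data)
  boxes <- list(cochlea = NULL, vestibule = rbind(c(1, 1, 1), d))
  sp <- split_compartments(els, boxes)
  expect_equal(sum(sp$cochlea$data), 0L)
  expect_identical(sp$vestibule$data, els$mask$data)
  overlap <- list(cochlea = rbind(c(1, 1, 1), c(4, 4, 4)),
                  vestibule = rbind(c(4, 4, 4), d))
  expect_error(split_compartments(els, overlap), "overlap")
})
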