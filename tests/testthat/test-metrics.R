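test_that("mask volume arithmetic", {
  expect_equal(els_volume(array(FALSE, c(4, 4, 4)), 0.25), 0)
  m <- array(FALSE, c(10, 10, 10)); m[1:10, 1:10, 1:10][1:1000] <- TRUE
  expect_equal(els_volume(m, 0.25), 15.625)
  # additivity over a disjoint split
  a <- array(runif(1000) > 0.5, c(10, 10, 10))
  b <- array(runif(1000) > 0.5, c(10, 10, 10)) & !a
  expect_equal(els_volume(a | b, 0.5), els_volume(a, 0.5) + els_volume(b, 0.5))
})

test_that("asymmetry index formula and antisymmetry", {
  expect_equal(asymmetry_index(12, 8), 20)
  expect_equal(asymmetry_index(5, 5), 0)
  expect_equal(asymmetry_index(10, 0), 100)
  expect_equal(asymmetry_index(0, 0), 0)
  for (r in c(0, 1, 3.7, 12)) for (l in c(0, 2, 9.1)) {
    expect_identical(asymmetry_index(r, l), -asymmetry_index(l, r))
  }
})

test_that("side difference and its TFS ratio", {
  expect_equal(unname(diff_and_ratio(5, 5, 100)), c(0, 0))
  dr <- diff_and_ratio(16.7, 8.7, 241.2)
  expect_equal(unname(dr["diff_mm3"]), 8, tolerance = 1e-12)
  expect_equal(round(unname(dr["diff_tfs_pct"]), 2), 3.32)
  # linearity: doubling both sides doubles Diff and the ratio at fixed TFS
  d1 <- diff_and_ratio(10, 6, 200)
  d2 <- diff_and_ratio(20, 12, 200)
  expect_equal(unname(d2), 2 * unname(d1))
  expect_error(diff_and_ratio(1, 2, 0))
})

test_that("vestibular grading thresholds", {
  expect_equal(grade_vestibule(0.20), 0L)
  expect_equal(grade_vestibule(0.40), 1L)
  expect_equal(grade_vestibule(0.60), 2L)
  # boundaries: exactly 1/3 is mild; exactly 50% is still mild
  expect_equal(grade_vestibule(1 / 3), 1L)
  expect_equal(grade_vestibule(0.5), 1L)
  expect_equal(grade_vestibule(0.5 + 1e-9), 2L)
  # monotone in the ratio
  expect_true(all(diff(grade_vestibule(seq(0, 1, by = 0.01))) >= 0))
})

test_that("cochlear grading: floor, equality, enlargement", {
  expect_equal(grade_cochlea(0, 10), 0L)
  expect_equal(grade_cochlea(10, 10), 1L)
  expect_equal(grade_cochlea(15, 10), 2L)
  expect_equal(grade_cochlea(0.5, 10, detection_floor = 1), 0L)
  expect_true(all(diff(grade_cochlea(0:20, rep(10, 21), 1)) >= 0))
})

test_that("grading slice selection: symmetry, slabs, degenerate inputs", {
  run <- small_run()
  hull <- run$result$hull$mask$data
  comp <- run$result$truth_analysis$compartment$data
  side <- hydroquant:::side_regions(dim(hull))
  sl_l <- select_grading_slices(hull, comp, side == 1L, slab_voxels = 2L)
  sl_r <- select_grading_slices(hull, comp, side == 2L, slab_voxels = 2L)
  expect_equal(unname(sl_l), unname(sl_r))  # mirror-symmetric phantom
  # single-slice compartment: that slice is selected
  d <- c(8, 8, 8)
  h1 <- array(FALSE, d); h1[4, 5, 4] <- TRUE; h1[5, 5, 5] <- TRUE
  cp <- array(0L, d); cp[4, 5, 4] <- 1L; cp[5, 5, 5] <- 2L
  sl <- select_grading_slices(h1, cp, array(TRUE, d))
  expect_equal(unname(sl["cochlear_slice"]), 5L)
  expect_equal(unname(sl["vestibular_slice"]), 5L)
  expect_error(select_grading_slices(h1, array(0L, d), array(TRUE, d)),
               "empty cochlear")
})

test_that("per-side measures and pairing are internally consistent", {
  run <- small_run()
  m <- run$result$measures
  expect_setequal(m$scope, c("ear", "cochlea", "vestibule"))
  expect_true(all(m$els_tfs_pct >= 0 & m$els_tfs_pct <= 100, na.rm = TRUE))
  # compartment ELS sums to at most the whole-ear ELS
  for (s in c("left", "right")) {
    ms <- m[m$side == s, ]
    expect_lte(ms$els_mm3[ms$scope == "cochlea"] + ms$els_mm3[ms$scope == "vestibule"],
               ms$els_mm3[ms$scope == "ear"] + 1e-9)
  }
  p <- run$result$pairs
  expect_equal(nrow(p), 3L)
  expect_true(all(p$diff_mm3 >= 0))
  expect_true(all(abs(p$ai_pct) <= 100))
  expect_equal(p$els_mean_mm3, (p$els_mm3_left + p$els_mm3_right) / 2)
  # swapping the leading side swaps ipsi/contra but not the AI
  p2 <- pair_measures(m, "left")
  expect_equal(p2$els_ipsi_mm3, p$els_contra_mm3)
  expect_equal(p2$ai_pct, p$ai_pct)
})
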