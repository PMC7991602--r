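test_that("Jongkees caloric asymmetry: symmetry, thirds, boundary, scaling", {
  expect_equal(caloric_asymmetry(20, 20, 20, 20)$ar_pct, 0)
  r <- caloric_asymmetry(20, 20, 10, 10)
  expect_equal(r$ar_pct, 100 / 3, tolerance = 1e-12)
  expect_equal(r$weaker_side, "left")       # right responses stronger
  b <- caloric_asymmetry(0, 0, 10, 10)
  expect_equal(b$ar_pct, 100)
  expect_equal(b$weaker_side, "right")
  # scale invariance
  expect_equal(caloric_asymmetry(8, 12, 5, 6)$ar_pct,
               caloric_asymmetry(80, 120, 50, 60)$ar_pct)
  expect_error(caloric_asymmetry(0, 0, 0, 0), "areflexia")
})

test_that("vestibular paresis cut-off is strictly greater than 35%", {
  expect_false(is_vestibular_paresis(35))
  expect_true(is_vestibular_paresis(36))
  expect_false(is_vestibular_paresis(0))
})

test_that("VEMP amplitude asymmetry ratio", {
  expect_equal(vemp_ar(15, 5), 50)
  expect_equal(vemp_ar(7, 7), 0)
  expect_equal(vemp_ar(10, 0), 100)
  expect_equal(vemp_ar(3, 1), vemp_ar(30, 10))  # scale invariance
  expect_error(vemp_ar(5, 10))
  expect_error(vemp_ar(0, 0))
})

normal_record <- function() {
  list(pta_right = 10, pta_left = 12,
       caloric_r30 = 10, caloric_r44 = 12, caloric_l30 = 11, caloric_l44 = 11,
       cvemp_p13_amp_right = 11, cvemp_p13_amp_left = 12,
       ovemp_n10_amp_right = 9, ovemp_n10_amp_left = 10,
       vhit_gain_right = 0.96, vhit_gain_left = 0.95)
}

test_that("deficit classification covers the exemplary case patterns", {
  # all normal
  expect_equal(classify_deficits(normal_record())$category, "normal")
  expect_equal(classify_deficits(normal_record())$laterality, "normal")

  # combined audio-vestibular case: PTA 36 dB right plus a large right-weaker
  # caloric asymmetry with normal vHIT
  rec <- normal_record()
  rec$pta_right <- 36
  rec$caloric_r30 <- 6; rec$caloric_r44 <- 6
  rec$caloric_l30 <- 14; rec$caloric_l44 <- 14   # signed -40%, right weaker
  out <- classify_deficits(rec)
  expect_equal(out$category, "vestibulocochlear")
  expect_equal(out$laterality, "right")

  # profound unilateral hearing loss with normal vestibular testing
  rec2 <- normal_record()
  rec2$pta_right <- 90
  out2 <- classify_deficits(rec2)
  expect_equal(out2$category, "cochlear")
  expect_equal(out2$laterality, "right")

  # VEMP-only vestibular deficit, left-smaller amplitude
  rec3 <- normal_record()
  rec3$cvemp_p13_amp_right <- 14; rec3$cvemp_p13_amp_left <- 4  # AR 55.6%
  out3 <- classify_deficits(rec3)
  expect_equal(out3$category, "vestibular")
  expect_equal(out3$laterality, "left")

  # bilateral: cochlear right + vestibular left
  rec4 <- rec3
  rec4$pta_right <- 40
  out4 <- classify_deficits(rec4)
  expect_equal(out4$category, "vestibulocochlear")
  expect_equal(out4$laterality, "bilateral")
})

test_that("classification is a pure function and reports missing fields", {
  rec <- normal_record()
  expect_identical(classify_deficits(rec), classify_deficits(rec[sample(names(rec))]))
  rec$pta_left <- NULL
  expect_error(classify_deficits(rec), "pta_left")
  rec2 <- normal_record(); rec2$vhit_gain_right <- NA
  expect_error(classify_deficits(rec2), "vhit_gain_right")
})

test_that("every cohort subject receives exactly one category and laterality", {
  co <- generate_cohort(c(VM = 6, MD = 6, `VM-MD` = 3), seed = 9L)
  cls <- purrr::map_dfr(seq_len(nrow(co)), function(i) classify_deficits(co[i, ]))
  expect_equal(nrow(cls), nrow(co))
  expect_true(all(cls$category %in% c("normal", "vestibular", "cochlear",
                                      "vestibulocochlear")))
  expect_true(all(cls$laterality %in% c("normal", "right", "left", "bilateral")))
  expect_identical(cls$category == "normal", cls$laterality == "normal")
})
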