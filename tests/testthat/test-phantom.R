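test_that("zero endolymph fraction yields no endolymph voxels", {
  sp <- small_spec(0, 0)
  m <- build_labyrinth(sp)
  expect_equal(sum(m$label$data == 2L), 0L)
})

test_that("requested fractions are recovered from the labels within 0.02", {
  for (f in c(0.1, 0.3, 0.5, 0.7)) {
    m <- build_labyrinth(small_spec(f, f))
    fr <- labyrinth_fractions(m)
    expect_true(all(abs(fr$fraction - f) <= 0.02),
                label = sprintf("fraction %.1f recovered", f))
  }
})

test_that("rasterised ellipsoid at fraction 0.5 lands in [0.48, 0.52]", {
  # vestibule-only check at finer resolution, per the stated geometry
  sp <- phantom_spec(
    grid_shape = c(40L, 40L, 72L), voxel_mm = 0.25, ear_offset_mm = 6,
    vestibule = list(semi_axes_mm = c(3, 2, 2), frac = c(0.5, 0.5)),
    cochlea = list(offset_mm = c(0, 0, 0), r_start_mm = 0.1, r_end_mm = 0.1,
                   turns = 1, tube_radius_mm = 0.05, rise_mm = 0.1,
                   frac = c(0, 0)),
    connector_radius_mm = 0
  )
  fr <- labyrinth_fractions(build_labyrinth(sp))
  vest <- fr[fr$compartment == "vestibule", ]
  expect_true(all(vest$fraction >= 0.48 & vest$fraction <= 0.52))
})

test_that("equal fractions give an exactly mirror-symmetric phantom", {
  m <- build_labyrinth(small_spec(0.3, 0.3))
  flip3 <- function(a) a[, , dim(a)[3]:1]
  expect_identical(flip3(m$label$data), m$label$data)
  fr <- labyrinth_fractions(m)
  counts <- tidyr::pivot_wider(fr[, c("side", "compartment", "endo_voxels")],
                               names_from = "side", values_from = "endo_voxels")
  expect_equal(counts$left, counts$right)
})

test_that("volume conservation: endolymph + perilymph = fluid, exactly", {
  m <- build_labyrinth(small_spec(0.4, 0.25))
  lab <- m$label$data
  expect_identical(sum(lab == 1L) + sum(lab == 2L), sum(lab > 0L))
  # endolymph only inside compartments; compartments only inside fluid
  expect_true(all(m$compartment$data[lab == 2L] > 0L))
  expect_true(all(lab[m$compartment$data > 0L] > 0L))
  # sides disjoint and cover the fluid
  expect_true(all(m$side$data[lab > 0L] %in% 1:2))
})

test_that("sequence simulation is seed-deterministic and polarity-correct", {
  sp <- small_spec(0.3, 0.3, noise = 3, seed = 42L)
  m <- build_labyrinth(sp)
  t1 <- simulate_sequences(m, sp)
  t2 <- simulate_sequences(m, sp)
  expect_identical(t1$mrc$data, t2$mrc$data)
  expect_identical(t1$ppi$data, t2$ppi$data)
  expect_identical(t1$pei$data, t2$pei$data)

  # noise-free polarity
  sp0 <- small_spec(0.3, 0.3, noise = 0)
  m0 <- build_labyrinth(sp0)
  tr <- simulate_sequences(m0, sp0)
  hyd <- tr$ppi$data - tr$pei$data
  expect_true(all(hyd[m0$label$data == 2L] < 0))
  expect_true(all(hyd[m0$label$data == 1L] > 0))
  # no endolymph: subtraction non-negative inside fluid
  spn <- small_spec(0, 0, noise = 0)
  mn <- build_labyrinth(spn)
  trn <- simulate_sequences(mn, spn)
  expect_true(all((trn$ppi$data - trn$pei$data)[mn$label$data > 0L] >= 0))
})

test_that("geometry exceeding the grid errors naming the axis", {
  expect_error(
    phantom_spec(grid_shape = c(20L, 48L, 84L), voxel_mm = 0.5),
    "axis 1"
  )
  expect_error(
    phantom_spec(ear_offset_mm = 40),
    "axis 3"
  )
})

test_that("geometry jitter moves both ears coherently", {
  sp <- small_spec(0.3, 0.3, noise = 0, seed = 5L, jitter_mm = 0.4)
  subj <- make_phantom_subject(sp)
  base <- build_labyrinth(small_spec(0.3, 0.3, noise = 0))
  expect_equal(sum(subj$truth$label$data > 0), sum(base$label$data > 0),
               tolerance = 0.05)
  expect_false(identical(subj$truth$label$data, base$label$data))
})
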