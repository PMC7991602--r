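# Shared fixtures: a reduced two-ear phantom (24 x 24 x 42 mm at 0.5 mm)
# that keeps every pipeline stage exercised while staying fast, plus
# independent brute-force oracles for the VOLT ensemble and the r x c
# Fisher test.

small_spec <- function(frac_vest = 0.3, frac_coch = frac_vest,
                       noise = 2, seed = 1L, jitter_mm = 0) {
  phantom_spec(
    grid_shape = c(48L, 48L, 84L), voxel_mm = 0.5,
    vestibule = list(semi_axes_mm = c(2.6, 2.2, 2.0),
                     frac = c(frac_vest, frac_vest)),
    cochlea = list(offset_mm = c(6.5, 0, 0), r_start_mm = 2.6, r_end_mm = 1.2,
                   turns = 2, tube_radius_mm = 0.7, rise_mm = 4,
                   frac = c(frac_coch, frac_coch)),
    noise_sd = c(mrc = noise, ppi = noise, pei = noise),
    jitter_mm = jitter_mm, seed = seed
  )
}

small_cfg <- function(seed = 1L) {
  run_config(preprocess = preprocess_config(crop_size_mm = c(20, 20, 38)),
             seed = seed)
}

# cache expensive shared objects across test files
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

small_atlas <- function() {
  cached("atlas", build_atlas(list(build_labyrinth(small_spec(0.3, seed = 1L)))))
}

# one full pipeline run on the reduced phantom (fraction 0.4), shared by
# several test files
small_run <- function() {
  cached("run40", {
    subj <- make_phantom_subject(small_spec(0.4, seed = 7L))
    r <- run_subject(subj$triplet, small_atlas(), small_cfg(),
                     truth = subj$truth)
    list(subject = subj, result = r)
  })
}

# --- independent VOLT oracle -------------------------------------------------
# recomputes, for every voxel and all 12 configurations, the masked window
# statistics directly from slice submatrices (no summed-area tables)
brute_volt_votes <- function(vals, hull, radii = c(6L, 10L),
                             k = -0.2, offset = 0) {
  d <- dim(vals)
  votes <- array(0L, dim = d)
  slice_of <- function(a, axis, s) {
    switch(axis, a[s, , ], a[, s, ], a[, , s])
  }
  for (axis in 1:3) {
    for (s in seq_len(d[axis])) {
      sl <- slice_of(vals, axis, s)
      hl <- slice_of(hull, axis, s)
      ds <- dim(sl)
      acc <- array(0L, ds)
      for (alg in c("niblack", "mean")) {
        for (r in radii) {
          for (i in seq_len(ds[1])) {
            ii <- max(1, i - r):min(ds[1], i + r)
            for (j in seq_len(ds[2])) {
              if (!hl[i, j]) next
              jj <- max(1, j - r):min(ds[2], j + r)
              w <- sl[ii, jj, drop = FALSE]
              hw <- hl[ii, jj, drop = FALSE]
              vs <- w[hw]
              mu <- sum(vs) / length(vs)
              thr <- if (alg == "niblack") {
                mu + k * sqrt(max(sum(vs * vs) / length(vs) - mu * mu, 0))
              } else {
                mu + offset
              }
              if (sl[i, j] < thr) acc[i, j] <- acc[i, j] + 1L
            }
          }
        }
      }
      if (axis == 1) votes[s, , ] <- votes[s, , ] + acc
      else if (axis == 2) votes[, s, ] <- votes[, s, ] + acc
      else votes[, , s] <- votes[, , s] + acc
    }
  }
  votes
}

# --- independent Fisher oracle ----------------------------------------------
# exhaustive enumeration of all tables with the observed margins (small
# tables only), summing the probabilities of tables no more probable than
# the observed one
enumerate_fisher_p <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  logp <- function(m) {
    sum(lfactorial(rs)) + sum(lfactorial(cs)) -
      lfactorial(sum(m)) - sum(lfactorial(m))
  }
  lp_obs <- logp(tab)
  total <- 0
  fill <- function(m, row, col) {
    if (row == nrow(tab)) {
      # last row is determined by the column margins
      last <- cs - colSums(m[seq_len(row - 1), , drop = FALSE])
      if (any(last < 0) || sum(last) != rs[row]) return()
      m[row, ] <- last
      lp <- logp(m)
      if (lp <= lp_obs + 1e-9) total <<- total + exp(lp)
      return()
    }
    if (col == ncol(tab)) {
      m[row, col] <- rs[row] - sum(m[row, seq_len(col - 1)])
      if (m[row, col] < 0) return()
      if (sum(m[seq_len(row), col]) > cs[col]) return()
      fill(m, row + 1L, 1L)
      return()
    }
    used_row <- if (col > 1) sum(m[row, seq_len(col - 1)]) else 0
    used_col <- if (row > 1) sum(m[seq_len(row - 1), col]) else 0
    for (v in 0:min(rs[row] - used_row, cs[col] - used_col)) {
      m[row, col] <- v
      fill(m, row, col + 1L)
    }
  }
  fill(matrix(0L, nrow(tab), ncol(tab)), 1L, 1L)
  min(total, 1)
}

# rotate a 3D array by 90 degrees about a grid axis
rot90_about <- function(a, axis) {
  if (axis == 1) {
    b <- aperm(a, c(1, 3, 2))
    b[, dim(b)[2]:1, , drop = FALSE]
  } else if (axis == 2) {
    b <- aperm(a, c(3, 2, 1))
    b[, , dim(b)[3]:1, drop = FALSE]
  } else {
    b <- aperm(a, c(2, 1, 3))
    b[dim(b)[1]:1, , , drop = FALSE]
  }
}

unrot90_about <- function(a, axis) {
  for (i in 1:3) a <- rot90_about(a, axis)
  a
}
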