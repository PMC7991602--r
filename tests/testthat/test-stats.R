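test_that("chi-square with phi: hand-computed and degenerate cases", {
  r <- chi_square(rbind(c(10, 0), c(0, 10)))
  expect_equal(r$statistic, 20)   # all expected counts are 5: 4 * 25/5
  expect_equal(r$df, 1)
  expect_equal(r$phi, 1)
  # independence: table proportional to its margins
  ind <- outer(c(10, 20), c(3, 7)) / 10
  r0 <- chi_square(ind)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$phi, 0, tolerance = 1e-9)
  expect_error(chi_square(rbind(c(0, 0), c(3, 4))), "zero margin")
})

test_that("phi is exactly invariant under count scaling", {
  tab <- rbind(c(4, 9, 2), c(7, 1, 6))
  r1 <- chi_square(tab)
  r5 <- chi_square(tab * 5L)
  expect_equal(r5$statistic, 5 * r1$statistic)
  expect_equal(r5$phi, r1$phi)
})

test_that("tidy/glance methods return one-row tibbles", {
  r <- chi_square(rbind(c(10, 0), c(0, 10)))
  expect_s3_class(tidy(r), "tbl_df")
  expect_equal(nrow(tidy(r)), 1L)
  expect_named(glance(r), names(tidy(r)))
})

test_that("exact Fisher agrees with exhaustive enumeration", {
  t1 <- rbind(c(3, 1), c(1, 3))
  expect_equal(fisher_exact_rxc(t1)$p_value, 0.4857143, tolerance = 1e-6)
  expect_equal(fisher_exact_rxc(t1)$p_value, enumerate_fisher_p(t1),
               tolerance = 1e-9)
  # degenerate single-row/column tables
  expect_equal(fisher_exact_rxc(matrix(c(2, 3, 4), 1))$p_value, 1)
  expect_equal(fisher_exact_rxc(matrix(c(2, 3, 4), 3))$p_value, 1)
  # property: random small tables (N <= 30) match the enumeration oracle
  set.seed(31)
  for (i in 1:8) {
    nr <- sample(2:3, 1); nc <- sample(2:3, 1)
    tab <- matrix(stats::rpois(nr * nc, 2.5), nr, nc)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || sum(tab) > 30) next
    expect_equal(fisher_exact_rxc(tab)$p_value, enumerate_fisher_p(tab),
                 tolerance = 1e-7, label = paste("table", i))
  }
  expect_error(
    fisher_exact_rxc(matrix(5L, 6, 6)),
    "monte_carlo"
  )
})

test_that("Monte-Carlo Fisher converges to the exact value", {
  tab <- rbind(c(8, 3, 2), c(2, 7, 4), c(3, 2, 9))  # 3x3, N = 40
  pe <- fisher_exact_rxc(tab, "exact")$p_value
  pm <- fisher_exact_rxc(tab, "monte_carlo", reps = 1e5, seed = 7L)
  expect_lte(abs(pm$p_value - pe), 3 * pm$mc_se + 1e-6)
  # seeded reproducibility
  pm2 <- fisher_exact_rxc(tab, "monte_carlo", reps = 1e5, seed = 7L)
  expect_identical(pm$p_value, pm2$p_value)
  expect_error(fisher_exact_rxc(tab, "monte_carlo"), "seed")
})

test_that("Spearman correlation: monotone extremes and the rank formula", {
  expect_equal(spearman_assoc(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_assoc(1:8, -(1:8))$rho, -1)
  r <- spearman_assoc(1:5, c(1, 3, 2, 5, 4))
  expect_equal(r$rho, 0.8)     # 1 - 6*4 / (5*24)
  expect_true(r$p_value > 0 && r$p_value <= 1)
})

test_that("ANOVA: two-group F equals t^2 and Bonferroni caps at 1", {
  set.seed(12)
  x <- rnorm(10); y <- rnorm(12, 0.4)
  a <- anova_bonferroni(c(x, y), rep(c("a", "b"), c(10, 12)))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(a$glance$f_statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a$glance$p_value, tt$p.value, tolerance = 1e-9)
  # three groups: adjusted p = min(1, raw * 3)
  g <- rep(c("a", "b", "c"), each = 8)
  v <- rnorm(24)
  a3 <- anova_bonferroni(v, g)
  raw <- stats::pairwise.t.test(v, g, p.adjust.method = "none")$p.value
  adj <- a3$pairwise
  for (k in seq_len(nrow(adj))) {
    r <- raw[adj$group1[k], adj$group2[k]]
    expect_equal(adj$p_adjusted[k], min(1, r * 3), tolerance = 1e-9)
  }
  expect_error(anova_bonferroni(1:5, rep("a", 5)), "2 groups")
})

test_that("ANOVA holds its size under the null", {
  # simulated null: identical means and variances
  set.seed(202)
  rej <- mean(replicate(4000, {
    v <- rnorm(24)
    anova_bonferroni(v, rep(c("a", "b", "c"), each = 8))$glance$p_value < 0.05
  }))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("group-symptom cross-tabulation matches the published coding", {
  # three-level tinnitus coding reproduces the published group table
  records <- tibble::tibble(
    group = rep(c("VM", "MD", "VM-MD"), c(25, 29, 8)),
    tinnitus = c(rep(c("none", "bilateral", "ipsilateral"), c(14, 7, 4)),
                 rep(c("none", "bilateral", "ipsilateral"), c(5, 4, 20)),
                 rep(c("none", "bilateral", "ipsilateral"), c(2, 1, 5)))
  )
  tab <- build_group_symptom_table(records, "tinnitus", "laterality")
  r <- chi_square(tab)
  expect_equal(r$df, 4)
  expect_equal(r$statistic, 16.3, tolerance = 0.05)
  # presence coding gives a groups x 2 table with df = 2
  records$headache <- records$group == "VM" |
    c(rep(FALSE, 25), rep(c(TRUE, FALSE), c(7, 22)), rep(c(TRUE, FALSE), c(5, 3)))
  tabp <- build_group_symptom_table(records, "headache", "presence")
  expect_equal(dim(unclass(tabp)), c(3L, 2L))
  expect_equal(chi_square(tabp)$df, 2)
  expect_error(build_group_symptom_table(records[0, ], "tinnitus", "laterality"),
               "no records")
})

test_that("bundled study tables load with consistent margins", {
  tabs <- eh_study_tables()
  expect_true(all(c("eh_presence_all", "tinnitus_all",
                    "eh_laterality_by_deficit_side") %in% names(tabs)))
  expect_equal(sum(tabs$eh_presence_all), 62L)
  expect_equal(sum(tabs$tinnitus_all), 62L)
  expect_equal(unname(rowSums(tabs$eh_presence_all)), c(25L, 29L, 8L))
  # column margins of the deficit cross-tabulations match their headers
  expect_equal(unname(colSums(tabs$eh_laterality_by_deficit_side)),
               c(28L, 12L, 16L, 6L))
  expect_equal(unname(colSums(tabs$eh_location_by_deficit)),
               c(24L, 13L, 12L, 13L))
})
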