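#' Contingency table of counts
#'
#' @param counts non-negative integer matrix.
#' @param row_labels,col_labels optional dimnames.
#' @return a `contingency_table` (an integer matrix with class attribute).
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  if (!is.null(row_labels)) rownames(counts) <- row_labels
  if (!is.null(col_labels)) colnames(counts) <- col_labels
  class(counts) <- c("contingency_table", class(counts))
  counts
}

#' Pearson chi-square test with the phi effect size
#'
#' Uncorrected Pearson statistic (no Yates continuity correction), p from
#' the chi-square distribution with `(r-1)(c-1)` degrees of freedom, and
#' `phi = sqrt(chi2 / N)`. For tables beyond 2x2 this is the
#' `sqrt(chi2/N)` convention (not Cramer's V), which is how the cohort
#' effect sizes are reported; phi is invariant under scaling all counts.
#'
#' @param tab matrix of counts (a [contingency_table()] or coercible).
#' @return a `chi_square_result` with `statistic`, `df`, `p_value`, `phi`,
#'   `n`.
#' @export
chi_square <- function(tab) {
  tab <- unclass(as.matrix(tab))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square undefined: table has a zero margin")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ht$expected <= 0)) stop("all expected counts must be positive")
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 phi = sqrt(unname(ht$statistic) / sum(tab)),
                 n = sum(tab), table = tab),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("chi-square(%d) = %.2f, p = %.3g, phi = %.2f (N = %d)\n",
              x$df, x$statistic, x$p_value, x$phi, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.chi_square_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 phi = x$phi, n = x$n, method = "Pearson chi-square (uncorrected)")
}

#' @exportS3Method generics::glance
glance.chi_square_result <- function(x, ...) tidy(x)

# log multivariate-hypergeometric probability of a table given its margins
log_table_prob <- function(tab) {
  sum(lfactorial(rowSums(tab))) + sum(lfactorial(colSums(tab))) -
    lfactorial(sum(tab)) - sum(lfactorial(tab))
}

#' Fisher's exact test for r x c tables
#'
#' `method = "exact"` uses the network (Mehta-Patel) algorithm of the
#' Freeman-Halton generalisation: the p-value sums the probabilities,
#' under the multivariate hypergeometric distribution with fixed margins,
#' of all tables no more probable than the observed one. Exact evaluation
#' is limited to tables up to `exact_limit` rows/columns and `n_limit`
#' total; larger tables must use `method = "monte_carlo"`, a seeded
#' fixed-margin sampler (Patefield's algorithm via [stats::r2dtable()])
#' with the add-one tie-inclusive estimator and a reported standard error.
#'
#' @param tab matrix of counts.
#' @param method `"exact"` or `"monte_carlo"`.
#' @param reps Monte-Carlo replicates.
#' @param seed Monte-Carlo seed (required for `"monte_carlo"`).
#' @param exact_limit,n_limit size guards for the exact method.
#' @return a `fisher_result` with `p_value`, `method`, and for Monte Carlo
#'   `mc_se`, `reps`, `seed`.
#' @export
fisher_exact_rxc <- function(tab, method = c("exact", "monte_carlo"),
                             reps = 1e6, seed = NULL,
                             exact_limit = 5L, n_limit = 100L) {
  method <- match.arg(method)
  tab <- unclass(as.matrix(tab))
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (nrow(tab) == 1L || ncol(tab) == 1L) {
    return(structure(list(p_value = 1, method = method),
                     class = "fisher_result"))
  }
  if (method == "exact") {
    if (nrow(tab) > exact_limit || ncol(tab) > exact_limit || sum(tab) > n_limit) {
      stop("table too large for exact evaluation; use method = \"monte_carlo\"")
    }
    p <- stats::fisher.test(tab, workspace = 2e7)$p.value
    return(structure(list(p_value = min(p, 1), method = "exact_network"),
                     class = "fisher_result"))
  }
  if (is.null(seed)) stop("monte_carlo requires a seed")
  lp_obs <- log_table_prob(tab)
  hits <- 0L
  withr::with_seed(seed, {
    done <- 0L
    block <- 1e4L
    while (done < reps) {
      b <- min(block, reps - done)
      sims <- stats::r2dtable(b, rowSums(tab), colSums(tab))
      lp <- vapply(sims, log_table_prob, numeric(1))
      hits <- hits + sum(lp <= lp_obs + 1e-7)
      done <- done + b
    }
  })
  p <- (hits + 1) / (reps + 1)
  structure(list(p_value = p, method = "monte_carlo",
                 mc_se = sqrt(p * (1 - p) / reps), reps = reps, seed = seed),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("Fisher exact (%s): p = %.4g\n", x$method, x$p_value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fisher_result <- function(x, ...) {
  tibble::tibble(p_value = x$p_value, method = x$method,
                 mc_se = x$mc_se %||% NA_real_)
}

#' Spearman rank correlation
#'
#' Tie-corrected two-sided Spearman correlation; exact permutation p for
#' n <= 9 without ties, otherwise the t approximation.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return tibble with `rho`, `p_value`, `n`.
#' @export
spearman_assoc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ht <- suppressWarnings(stats::cor.test(
    x, y, method = "spearman",
    exact = length(x) <= 9 && !has_ties
  ))
  tibble::tibble(rho = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' @param values numeric response.
#' @param groups factor/character group labels (>= 2 groups with >= 2
#'   values each).
#' @return list with `glance` (one-row tibble: `f_statistic`, `df_between`,
#'   `df_within`, `p_value`) and `pairwise` (tibble of Bonferroni-adjusted
#'   pairwise p-values, raw p multiplied by the number of comparisons and
#'   capped at 1).
#' @export
anova_bonferroni <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 values")
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  gl <- tibble::tibble(
    f_statistic = s$`F value`[1],
    df_between = s$Df[1], df_within = s$Df[2],
    p_value = s$`Pr(>F)`[1]
  )
  pw <- stats::pairwise.t.test(values, groups, p.adjust.method = "bonferroni")
  pm <- pw$p.value
  pairs <- tidyr::pivot_longer(
    tibble::as_tibble(pm, rownames = "group1"),
    cols = -"group1", names_to = "group2", values_to = "p_adjusted"
  )
  pairs <- dplyr::filter(pairs, !is.na(.data$p_adjusted))
  list(glance = gl, pairwise = pairs)
}

#' Cross-tabulate diagnosis group against a symptom coding
#'
#' Builds the contingency tables behind the group-association chi-square
#' results: `coding = "presence"` gives a groups x {present, absent}
#' table (df = groups - 1), `coding = "laterality"` a groups x
#' {none, bilateral, ipsilateral} table (df = 2 (groups - 1)).
#'
#' @param records tibble with a `group` column and the symptom column.
#' @param symptom name of the symptom column; logical for presence coding,
#'   or one of `"none"`, `"bilateral"`, `"ipsilateral"` for the
#'   three-level coding.
#' @param coding `"presence"` or `"laterality"`.
#' @return a [contingency_table()].
#' @export
build_group_symptom_table <- function(records, symptom,
                                      coding = c("presence", "laterality")) {
  coding <- match.arg(coding)
  if (nrow(records) == 0L) stop("no records to tabulate")
  v <- records[[symptom]]
  if (is.null(v)) stop(sprintf("no column `%s` in records", symptom))
  if (coding == "presence") {
    cat_v <- factor(ifelse(as.logical(v), "present", "absent"),
                    levels = c("present", "absent"))
  } else {
    cat_v <- factor(v, levels = c("none", "bilateral", "ipsilateral"))
    if (any(is.na(cat_v))) stop("laterality coding expects none/bilateral/ipsilateral")
  }
  tab <- table(records$group, cat_v)
  contingency_table(unclass(as.matrix(tab)),
                    row_labels = rownames(tab), col_labels = colnames(tab))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
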