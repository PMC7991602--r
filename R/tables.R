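#' Bundled cohort count tables
#'
#' The published cross-tabulations of the VM / MD / VM-MD study cohort
#' (hydrops presence and symptom counts by diagnosis group, and the
#' EH-location / EH-laterality against neurophysiological deficit
#' classifications), transcribed cell by cell into
#' `inst/extdata/printed_tables.csv` with a note per cell. Two of the
#' transcribed rows sum to 35 and 34 respectively where the group totals
#' elsewhere are 62; the tables are used exactly as printed, without
#' reconciliation.
#'
#' @return named list of [contingency_table()] matrices.
#' @export
eh_study_tables <- function() {
  path <- system.file("extdata", "printed_tables.csv", package = "hydroquant")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$table), function(d) {
    rows <- unique(d$row)
    cols <- unique(d$col)
    m <- matrix(0L, nrow = length(rows), ncol = length(cols),
                dimnames = list(rows, cols))
    m[cbind(match(d$row, rows), match(d$col, cols))] <- d$count
    contingency_table(m)
  })
  out[unique(df$table)]
}

#' Recompute the cohort association statistics from the bundled tables
#'
#' Runs the uncorrected chi-square with phi on the group-association
#' tables and the exact r x c Fisher test on the two
#' deficit cross-tabulations, returning everything in one tidy table.
#'
#' @return tibble with one row per test: `table`, `test`, `statistic`,
#'   `df`, `p_value`, `phi`.
#' @export
reproduce_table_stats <- function() {
  tabs <- eh_study_tables()
  chi_tables <- c("eh_presence_all", "eh_presence_definite",
                  "headache_all", "headache_definite", "tinnitus_all")
  chi <- purrr::map_dfr(chi_tables, function(nm) {
    r <- chi_square(tabs[[nm]])
    tibble::tibble(table = nm, test = "chi_square",
                   statistic = r$statistic, df = r$df,
                   p_value = r$p_value, phi = r$phi)
  })
  fisher_tables <- c("eh_location_by_deficit", "eh_laterality_by_deficit_side")
  fis <- purrr::map_dfr(fisher_tables, function(nm) {
    r <- fisher_exact_rxc(tabs[[nm]], method = "exact")
    tibble::tibble(table = nm, test = "fisher_exact",
                   statistic = NA_real_, df = NA_real_,
                   p_value = r$p_value, phi = NA_real_)
  })
  dplyr::bind_rows(chi, fis)
}

#' Hydrops prevalence from a presence table
#'
#' Percentage of subjects with hydrops in one group row of a
#' presence/absence table.
#'
#' @param tab a presence/absence [contingency_table()] with columns
#'   `present` and `absent`.
#' @param group row name.
#' @return percentage in `[0, 100]`.
#' @export
eh_prevalence_pct <- function(tab, group) {
  row <- unclass(tab)[group, ]
  100 * row[["present"]] / sum(row)
}
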