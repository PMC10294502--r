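# Accessors for the published reference tables shipped under extdata/:
# the mined AG/IG rule tables, the per-disease frequency comparison counts,
# and the participant-characteristics counts reported for the 2020 KHPS
# cohort of 8477 participants aged over 45. These are transcriptions of
# published summary tables, not microdata; they serve as worked-example
# inputs and test fixtures, since the survey microdata are access-restricted.

#' Published reference rule tables for the 2020 KHPS cohort
#'
#' The association rules reported for the active (AG, 23 rules) and inactive
#' (IG, 37 rules) exercise strata, with confidence, support and lift as
#' printed (2 decimals) and an `exclusive` flag marking rules reported as
#' appearing only in that stratum's table.
#'
#' @param stratum `"AG"` or `"IG"`.
#' @return A rule tibble (see [read_rule_table()]).
#' @export
khps_reference_rules <- function(stratum = c("AG", "IG")) {
  stratum <- match.arg(stratum)
  file <- paste0("khps2020_", tolower(stratum), "_rules.csv")
  read_rule_table(
    system.file("extdata", file, package = "mcdrules"),
    stratum = stratum
  )
}

#' Published per-disease appearance counts for the 2020 KHPS rule sets
#'
#' The reported consequent/antecedent/total appearance counts per disease in
#' the AG and IG rule sets (the frequency-comparison table). Note that for a
#' few diseases the reported AG antecedent counts differ from a direct
#' recount of the printed AG rule table; these are the values as published.
#'
#' @return Tibble with columns `disease`, `AG_consequent`, `AG_antecedent`,
#'   `AG_total`, `IG_consequent`, `IG_antecedent`, `IG_total`.
#' @export
khps_reference_counts <- function() {
  readr::read_csv(
    system.file("extdata", "khps2020_frequency_counts.csv",
      package = "mcdrules"
    ),
    show_col_types = FALSE
  )
}

#' Published participant-characteristics counts for the 2020 KHPS cohort
#'
#' Category sizes and MCD counts per demographic variable (sex, age band,
#' education, regular exercise) plus the overall totals (8477 participants,
#' 3317 with MCD).
#'
#' @return Tibble with columns `variable`, `category`, `n`, `mcd_n`.
#' @export
khps_reference_characteristics <- function() {
  readr::read_csv(
    system.file("extdata", "khps2020_characteristics.csv",
      package = "mcdrules"
    ),
    show_col_types = FALSE
  )
}
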