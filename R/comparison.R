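# Rule-set comparison between exercise strata: shared vs exclusive rules,
# per-disease appearance counts, and the percentage-increase statistic.

#' Diff two rule sets by signature
#'
#' Rules are matched on [rule_signature()] (antecedent set + consequent);
#' metrics are ignored. The three parts partition the union of signatures.
#'
#' @param first,second Deduplicated rule tibbles (e.g. AG and IG).
#' @return A list of class `"ruleset_diff"` with elements `shared` (rows of
#'   `first`), `first_only`, `second_only`, and the two stratum labels.
#' @export
diff_rulesets <- function(first, second) {
  sig1 <- rule_signature(first)
  sig2 <- rule_signature(second)
  structure(
    list(
      shared = first[sig1 %in% sig2, , drop = FALSE],
      first_only = first[!sig1 %in% sig2, , drop = FALSE],
      second_only = second[!sig2 %in% sig1, , drop = FALSE],
      labels = c(
        attr(first, "stratum") %||% "first",
        attr(second, "stratum") %||% "second"
      )
    ),
    class = "ruleset_diff"
  )
}

#' @export
print.ruleset_diff <- function(x, ...) {
  cat("<ruleset_diff> ", x$labels[1], " vs ", x$labels[2], ": ",
    nrow(x$shared), " shared, ", nrow(x$first_only), " only in ",
    x$labels[1], ", ", nrow(x$second_only), " only in ", x$labels[2], "\n",
    sep = ""
  )
  invisible(x)
}

#' Per-disease appearance counts in a rule set
#'
#' For each disease: the number of rules with it as the consequent, the
#' number of rules containing it in the antecedent, and their sum. Each rule
#' contributes at most one consequent increment and one antecedent increment
#' per disease.
#'
#' @param rules A (deduplicated) rule tibble.
#' @param vocabulary Diseases to report rows for; defaults to every disease
#'   appearing in the rules.
#' @return Tibble with columns `disease`, `n_consequent`, `n_antecedent`,
#'   `n_total`.
#' @export
count_appearances <- function(rules, vocabulary = NULL) {
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(c(
      rules$consequent,
      unlist(rules$antecedent)
    )))
  }
  n_con <- vapply(vocabulary, function(d) {
    sum(rules$consequent == d)
  }, integer(1), USE.NAMES = FALSE)
  n_ant <- vapply(vocabulary, function(d) {
    sum(vapply(rules$antecedent, function(a) d %in% a, logical(1)))
  }, integer(1), USE.NAMES = FALSE)
  tibble::tibble(
    disease = vocabulary,
    n_consequent = n_con,
    n_antecedent = n_ant,
    n_total = n_con + n_ant
  )
}

#' Percentage increase from a to b
#'
#' The frequency-increase statistic `100 * (b - a) / a`, rounded to the
#' nearest integer. Undefined when `a` is zero (reported as `NA`; rendered
#' as `"-"` in formatted tables).
#'
#' @param a,b Nonnegative counts (baseline and comparison).
#' @param digits Rounding digits, default 0 (nearest integer).
#' @return Numeric vector of percentages, `NA` where `a == 0`.
#' @export
#' @examples
#' percent_increase(23, 37) # 61
percent_increase <- function(a, b, digits = 0) {
  out <- ifelse(a > 0, round(100 * (b - a) / a, digits), NA_real_)
  as.numeric(out)
}

#' Disease-frequency comparison table between two rule sets
#'
#' The Table-4-shaped summary: per disease, consequent/antecedent/total
#' appearance counts in each rule set and the percentage increase of the
#' totals from the first set to the second. Diseases absent from both rule
#' sets are dropped.
#'
#' @param first,second Deduplicated rule tibbles (baseline first, e.g. AG).
#' @param labels Column-prefix labels for the two sets.
#' @return Tibble with per-disease counts for both sets and `increase_pct`,
#'   plus an `"overall"` attribute holding the two rule counts and their
#'   percentage increase.
#' @export
frequency_table <- function(first, second, labels = c("AG", "IG")) {
  vocab <- sort(unique(c(
    first$consequent, unlist(first$antecedent),
    second$consequent, unlist(second$antecedent)
  )))
  a <- count_appearances(first, vocab)
  b <- count_appearances(second, vocab)
  out <- tibble::tibble(
    disease = vocab,
    a_consequent = a$n_consequent,
    a_antecedent = a$n_antecedent,
    a_total = a$n_total,
    b_consequent = b$n_consequent,
    b_antecedent = b$n_antecedent,
    b_total = b$n_total,
    increase_pct = percent_increase(a$n_total, b$n_total)
  )
  names(out) <- c(
    "disease",
    paste0(labels[1], c("_consequent", "_antecedent", "_total")),
    paste0(labels[2], c("_consequent", "_antecedent", "_total")),
    "increase_pct"
  )
  out <- out[order(-out[[paste0(labels[2], "_total")]], out$disease), ]
  attr(out, "overall") <- c(
    stats::setNames(c(nrow(first), nrow(second)), labels),
    increase_pct = percent_increase(nrow(first), nrow(second))
  )
  out
}
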