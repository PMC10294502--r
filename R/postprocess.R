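# Rule post-processing: canonical signatures, symmetric-pair deduplication,
# and rule-order classification.

#' Canonical rule signature
#'
#' A signature identifies a rule by its antecedent set and consequent only,
#' ignoring the metrics: `"a+b => c"` with the antecedent sorted. Two rules
#' are the same association iff their signatures are equal.
#'
#' @param rules A rule tibble (or a list with `antecedent`/`consequent`).
#' @return Character vector of signatures, one per rule.
#' @export
rule_signature <- function(rules) {
  if (!nrow(rules)) {
    return(character())
  }
  paste0(
    vapply(rules$antecedent, function(a) paste(sort(a), collapse = "+"), ""),
    " => ", rules$consequent
  )
}

#' Remove symmetric duplicate pair rules
#'
#' Among two-variable rules, (A -> B) and (B -> A) describe the same
#' co-occurrence and carry no additional predictive power, so when both are
#' present only the one with the higher confidence is retained. Confidence
#' ties are broken by keeping the rule whose consequent code sorts first, so
#' the result does not depend on input order. Rules of order three or more
#' are left untouched.
#'
#' @param rules A rule tibble from one stratum.
#' @return The rule tibble with the lower-confidence member of each
#'   symmetric order-2 pair removed, in canonical order.
#' @export
#' @examples
#' # of (A -> B, conf 60) and (B -> A, conf 50), only A -> B survives
dedup_symmetric_pairs <- function(rules) {
  if (!nrow(rules)) {
    return(rules)
  }
  ord <- vapply(rules$antecedent, length, integer(1)) + 1L
  pair_idx <- which(ord == 2L)
  if (length(pair_idx) < 2) {
    return(rules)
  }
  pair_key <- vapply(pair_idx, function(i) {
    paste(sort(c(rules$antecedent[[i]], rules$consequent[i])),
      collapse = "+"
    )
  }, "")
  drop <- integer()
  for (grp in split(pair_idx, pair_key)) {
    if (length(grp) < 2) next
    conf <- rules$confidence_pct[grp]
    cons <- rules$consequent[grp]
    keep <- grp[order(-conf, cons)][1]
    drop <- c(drop, setdiff(grp, keep))
  }
  if (!length(drop)) {
    return(rules)
  }
  out <- rules[-drop, , drop = FALSE]
  attr(out, "n") <- attr(rules, "n")
  attr(out, "stratum") <- attr(rules, "stratum")
  out
}

#' Rule order (number of variables involved)
#'
#' A rule's order is the number of distinct conditions it involves:
#' antecedent size plus one. A two-variable rule is a pair rule, a
#' four-variable rule has three antecedent conditions, and so on.
#'
#' @param rules A rule tibble.
#' @param labelled Return English labels (`"two-variable"`, ...) instead of
#'   integers.
#' @return Integer vector of orders, or a character vector when `labelled`.
#' @export
rule_order <- function(rules, labelled = FALSE) {
  ord <- vapply(rules$antecedent, length, integer(1)) + 1L
  if (!labelled) {
    return(ord)
  }
  words <- c(
    "one", "two", "three", "four", "five", "six", "seven", "eight",
    "nine", "ten"
  )
  lab <- ifelse(ord <= length(words), words[pmin(ord, length(words))],
    as.character(ord)
  )
  paste0(lab, "-variable")
}

#' Write a rule table to CSV
#'
#' Mirrors the published rule-table layout: consequent, semicolon-joined
#' antecedent, confidence, support (both percent, rounded to 2 decimals) and
#' lift (rounded to 2 decimals).
#'
#' @param rules A rule tibble.
#' @param path Output CSV path.
#' @param digits Decimal places for the reported metrics.
#' @export
write_rules <- function(rules, path, digits = 2) {
  out <- tibble::tibble(
    consequent = rules$consequent,
    antecedent = vapply(rules$antecedent, function(a) {
      paste(sort(a), collapse = ";")
    }, ""),
    confidence_pct = round(rules$confidence_pct, digits),
    support_pct = round(rules$support_pct, digits),
    lift = round(rules$lift, digits)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a rule table from CSV
#'
#' Inverse of [write_rules()]; also reads the reference rule-table fixtures
#' shipped under `extdata/` (which carry an extra `exclusive` flag column).
#'
#' @param path CSV path with columns `consequent`, `antecedent`
#'   (semicolon-joined), `confidence_pct`, `support_pct`, `lift`.
#' @param stratum Optional stratum label recorded on the result.
#' @return A rule tibble (without count columns).
#' @export
read_rule_table <- function(path, stratum = NA_character_) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  out <- tibble::tibble(
    consequent = raw$consequent,
    antecedent = lapply(strsplit(raw$antecedent, ";", fixed = TRUE), sort),
    order = lengths(strsplit(raw$antecedent, ";", fixed = TRUE)) + 1L,
    support_pct = raw$support_pct,
    confidence_pct = raw$confidence_pct,
    lift = raw$lift
  )
  if ("exclusive" %in% names(raw)) {
    out$exclusive <- as.logical(raw$exclusive)
  }
  out <- out[order(out$consequent, vapply(out$antecedent, itemset_key, "")), ]
  attr(out, "stratum") <- stratum
  out
}
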