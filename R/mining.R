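# Association-rule mining: level-wise Apriori frequent-itemset enumeration
# and rule generation under support / confidence / lift thresholds, plus an
# exhaustive brute-force reference path used as a testing oracle.
#
# All threshold comparisons are done on integer occurrence counts
# (e.g. 100 * count >= min_support_pct * n) rather than on rounded
# percentages, so rules sitting exactly at a threshold are classified
# consistently.

#' Construct a transaction set
#'
#' A transaction is one participant's set of present conditions; the
#' transaction set is the per-stratum input to the mining functions.
#'
#' @param sets List of character vectors (one set of condition codes per
#'   participant; empty sets allowed).
#' @param stratum Optional stratum label (e.g. `"AG"` or `"IG"`).
#' @param vocabulary Optional item vocabulary; items outside it raise an
#'   error. Defaults to the union of the observed items.
#' @return An object of class `"transaction_set"` with elements `sets`, `n`,
#'   `stratum`, `items`.
#' @export
transactions <- function(sets, stratum = NA_character_, vocabulary = NULL) {
  stopifnot(is.list(sets))
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  observed <- sort(unique(unlist(sets)))
  if (!is.null(vocabulary)) {
    bad <- setdiff(observed, vocabulary)
    if (length(bad)) {
      stop("transaction items outside the vocabulary: ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  structure(
    list(
      sets = sets, n = length(sets), stratum = stratum,
      items = observed
    ),
    class = "transaction_set"
  )
}

#' @export
print.transaction_set <- function(x, ...) {
  cat(
    "<transaction_set> ", x$n, " transactions, ", length(x$items),
    " items", if (!is.na(x$stratum)) paste0(" [", x$stratum, "]"), "\n",
    sep = ""
  )
  invisible(x)
}

#' Split condition profiles into per-stratum transaction sets
#'
#' @param profiles Profile tibble from [build_profiles()].
#' @return Named list of `transaction_set` objects, one per stratum present
#'   (typically `AG` and `IG`).
#' @export
profile_transactions <- function(profiles) {
  strata <- split(profiles$conditions, profiles$stratum)
  lapply_names <- names(strata)
  out <- lapply(lapply_names, function(s) {
    transactions(strata[[s]],
      stratum = s,
      vocabulary = condition_vocabulary()
    )
  })
  stats::setNames(out, lapply_names)
}

#' Mining thresholds
#'
#' Defaults follow the analysis settings: minimum rule support 1.5% of the
#' stratum, minimum confidence 20%, lift strictly greater than 1.5, and at
#' most 5 antecedent items. `support_on` selects whether the support
#' threshold applies to the joint (rule) support — the default, consistent
#' with the smallest reported rule supports — or to the antecedent support,
#' the dialect of some mining tools.
#'
#' @param min_support_pct Minimum support, percent (inclusive).
#' @param min_confidence_pct Minimum confidence, percent (inclusive).
#' @param min_lift Lift threshold (strict: rules need lift > `min_lift`).
#' @param max_antecedents Maximum antecedent set size.
#' @param support_on `"rule"` (joint support of antecedent and consequent)
#'   or `"antecedent"`.
#' @return A list of class `"mining_config"`.
#' @export
mining_config <- function(min_support_pct = 1.5, min_confidence_pct = 20,
                          min_lift = 1.5, max_antecedents = 5,
                          support_on = c("rule", "antecedent")) {
  support_on <- match.arg(support_on)
  stopifnot(
    min_support_pct > 0, min_confidence_pct > 0, min_lift > 0,
    max_antecedents >= 1
  )
  structure(
    list(
      min_support_pct = min_support_pct,
      min_confidence_pct = min_confidence_pct,
      min_lift = min_lift,
      max_antecedents = max_antecedents,
      support_on = support_on
    ),
    class = "mining_config"
  )
}

transaction_matrix <- function(tx) {
  p <- length(tx$items)
  mat <- matrix(FALSE, nrow = tx$n, ncol = p,
    dimnames = list(NULL, tx$items)
  )
  for (i in seq_len(tx$n)) {
    mat[i, match(tx$sets[[i]], tx$items)] <- TRUE
  }
  mat
}

itemset_key <- function(items) paste(items, collapse = "")

#' Enumerate frequent itemsets with Apriori
#'
#' Level-wise candidate generation: frequent size-k itemsets sharing their
#' first k-1 items are joined into size-(k+1) candidates, candidates with any
#' infrequent k-subset are pruned (downward closure), and surviving
#' candidates are counted against the transactions.
#'
#' @param tx A [transactions()] object.
#' @param min_support_pct Minimum support in percent of the stratum size
#'   (inclusive).
#' @param max_size Largest itemset size to enumerate (`Inf` for no cap).
#' @return Tibble with columns `items` (list of sorted character vectors),
#'   `size`, `count` and `support_pct`, in canonical (size, lexicographic)
#'   order.
#' @export
mine_frequent_itemsets <- function(tx, min_support_pct = 1.5,
                                   max_size = Inf) {
  stopifnot(inherits(tx, "transaction_set"))
  if (tx$n < 1) stop("empty transaction set", call. = FALSE)
  if (max_size < 1) stop("max_size must be at least 1", call. = FALSE)
  stopifnot(min_support_pct > 0)
  n <- tx$n
  mat <- transaction_matrix(tx)
  meets <- function(count) 100 * count >= min_support_pct * n

  counts1 <- colSums(mat)
  keep1 <- which(meets(counts1))
  level_sets <- lapply(keep1, identity) # integer column indices
  level_counts <- as.integer(counts1[keep1])
  all_sets <- level_sets
  all_counts <- level_counts

  frequent_keys <- new.env(parent = emptyenv())
  for (s in level_sets) assign(paste(s, collapse = ","), TRUE, frequent_keys)

  k <- 1L
  while (length(level_sets) >= 2 && k < max_size) {
    candidates <- apriori_join(level_sets, frequent_keys)
    if (!length(candidates)) break
    counts <- vapply(candidates, function(cand) {
      sum(rowSums(mat[, cand, drop = FALSE]) == length(cand))
    }, numeric(1))
    keep <- meets(counts)
    level_sets <- candidates[keep]
    level_counts <- as.integer(counts[keep])
    for (s in level_sets) {
      assign(paste(s, collapse = ","), TRUE, frequent_keys)
    }
    all_sets <- c(all_sets, level_sets)
    all_counts <- c(all_counts, level_counts)
    k <- k + 1L
  }

  items <- lapply(all_sets, function(s) tx$items[s])
  out <- tibble::tibble(
    items = items,
    size = lengths(items),
    count = all_counts,
    support_pct = 100 * all_counts / n
  )
  ord <- order(out$size, vapply(out$items, itemset_key, ""))
  out <- out[ord, ]
  attr(out, "n") <- n
  attr(out, "min_support_pct") <- min_support_pct
  out
}

# Join frequent k-itemsets sharing their first k-1 elements; prune candidates
# with an infrequent k-subset.
apriori_join <- function(level_sets, frequent_keys) {
  k <- length(level_sets[[1]])
  prefix <- vapply(level_sets, function(s) {
    paste(s[-k], collapse = ",")
  }, "")
  last <- vapply(level_sets, function(s) s[k], integer(1))
  candidates <- list()
  for (grp in split(seq_along(level_sets), prefix)) {
    if (length(grp) < 2) next
    lasts <- sort(last[grp])
    base <- level_sets[[grp[1]]][-k]
    pairs <- utils::combn(lasts, 2, simplify = FALSE)
    for (pr in pairs) {
      cand <- c(base, pr)
      ok <- all(vapply(seq_along(cand), function(i) {
        exists(paste(cand[-i], collapse = ","), frequent_keys)
      }, logical(1)))
      if (ok) candidates[[length(candidates) + 1L]] <- cand
    }
  }
  candidates
}

empty_rule_set <- function(stratum = NA_character_, n = 0L) {
  out <- tibble::tibble(
    consequent = character(),
    antecedent = list(),
    order = integer(),
    count = integer(),
    count_antecedent = integer(),
    count_consequent = integer(),
    support_pct = numeric(),
    confidence_pct = numeric(),
    lift = numeric()
  )
  attr(out, "n") <- n
  attr(out, "stratum") <- stratum
  out
}

#' Generate association rules from frequent itemsets
#'
#' Every frequent itemset of size >= 2 is split into each possible
#' single-item consequent B with antecedent A = itemset \ B. A rule is
#' emitted when it meets the support threshold (joint or antecedent support,
#' per `config$support_on`), confidence >= the confidence threshold, lift
#' strictly greater than the lift threshold, and |A| <= the antecedent cap.
#'
#' Metrics: support = 100 P(A,B); confidence = 100 P(A,B)/P(A);
#' lift = confidence / (100 P(B)). Values are kept unrounded; round on
#' output (see [write_rules()]).
#'
#' @param frequent Frequent itemsets from [mine_frequent_itemsets()],
#'   enumerated at (or below) the support threshold in `config`.
#' @param tx The transaction set the itemsets were counted on.
#' @param config A [mining_config()].
#' @return A rule tibble sorted by (consequent, antecedent), with attributes
#'   `n` and `stratum`.
#' @export
derive_rules <- function(frequent, tx, config = mining_config()) {
  stopifnot(inherits(tx, "transaction_set"))
  n <- tx$n
  counts <- stats::setNames(
    frequent$count,
    vapply(frequent$items, itemset_key, "")
  )
  rows <- list()
  big <- frequent[frequent$size >= 2, , drop = FALSE]
  for (i in seq_len(nrow(big))) {
    items <- big$items[[i]]
    c_ab <- big$count[i]
    for (b in items) {
      a <- setdiff(items, b)
      if (length(a) > config$max_antecedents) next
      c_a <- counts[[itemset_key(a)]]
      c_b <- counts[[itemset_key(b)]]
      if (is.null(c_a) || is.null(c_b) || c_b == 0) {
        stop("internal error: subset of a frequent itemset not counted",
          call. = FALSE
        )
      }
      sup_ok <- if (config$support_on == "rule") {
        100 * c_ab >= config$min_support_pct * n
      } else {
        100 * c_a >= config$min_support_pct * n
      }
      if (!sup_ok) next
      if (!(100 * c_ab >= config$min_confidence_pct * c_a)) next
      if (!(c_ab * n > config$min_lift * c_a * c_b)) next
      rows[[length(rows) + 1L]] <- list(
        consequent = b, antecedent = a,
        count = c_ab, count_antecedent = c_a, count_consequent = c_b
      )
    }
  }
  if (!length(rows)) {
    return(empty_rule_set(tx$stratum, n))
  }
  out <- tibble::tibble(
    consequent = vapply(rows, `[[`, "", "consequent"),
    antecedent = lapply(rows, `[[`, "antecedent"),
    order = vapply(rows, function(r) length(r$antecedent) + 1L, integer(1)),
    count = vapply(rows, function(r) as.integer(r$count), integer(1)),
    count_antecedent = vapply(rows, function(r) {
      as.integer(r$count_antecedent)
    }, integer(1)),
    count_consequent = vapply(rows, function(r) {
      as.integer(r$count_consequent)
    }, integer(1))
  )
  out$support_pct <- 100 * out$count / n
  out$confidence_pct <- 100 * out$count / out$count_antecedent
  out$lift <- out$count * n / (out$count_antecedent * out$count_consequent)
  out <- out[order(out$consequent, vapply(out$antecedent, itemset_key, "")), ]
  out <- out[, c(
    "consequent", "antecedent", "order", "count", "count_antecedent",
    "count_consequent", "support_pct", "confidence_pct", "lift"
  )]
  attr(out, "n") <- n
  attr(out, "stratum") <- tx$stratum
  out
}

#' Mine association rules (Apriori path)
#'
#' Convenience wrapper: enumerates frequent itemsets at the support threshold
#' implied by `config` and derives rules from them. With
#' `support_on = "antecedent"` the enumeration threshold is lowered to
#' `min_support_pct * min_confidence_pct / 100` so that every rule whose
#' antecedent meets the threshold and whose confidence can pass is reachable.
#'
#' @inheritParams derive_rules
#' @return A rule tibble, see [derive_rules()].
#' @export
#' @examples
#' tx <- transactions(list(
#'   c("H", "D"), c("H", "D", "S"), "H", "D", "S"
#' ))
#' mine_rules(tx, mining_config(min_support_pct = 40, min_confidence_pct = 50,
#'   min_lift = 1.0))
mine_rules <- function(tx, config = mining_config()) {
  effective_support <- if (config$support_on == "rule") {
    config$min_support_pct
  } else {
    config$min_support_pct * config$min_confidence_pct / 100
  }
  frequent <- mine_frequent_itemsets(tx,
    min_support_pct = effective_support,
    max_size = config$max_antecedents + 1
  )
  derive_rules(frequent, tx, config)
}

#' Brute-force rule enumeration (testing oracle)
#'
#' Counts every itemset over the observed vocabulary directly — transactions
#' are encoded as bitmasks and subset counts obtained with a superset-sum
#' transform — then applies exactly the same thresholds as [derive_rules()].
#' No Apriori pruning is involved, so this path serves as an independent
#' oracle for the main miner. Refuses vocabularies larger than 18 items.
#'
#' @inheritParams derive_rules
#' @return A rule tibble in the same canonical order as [mine_rules()].
#' @export
brute_force_rules <- function(tx, config = mining_config()) {
  stopifnot(inherits(tx, "transaction_set"))
  if (tx$n < 1) stop("empty transaction set", call. = FALSE)
  items <- tx$items
  k <- length(items)
  if (k > 18) {
    stop("brute-force enumeration refuses vocabularies over 18 items",
      call. = FALSE
    )
  }
  if (k == 0) {
    return(empty_rule_set(tx$stratum, tx$n))
  }
  n <- tx$n
  bit <- 2^(seq_len(k) - 1)
  masks <- vapply(tx$sets, function(s) {
    sum(bit[match(s, items)])
  }, numeric(1))
  total <- 2^k
  # f[s + 1] = number of transactions whose item mask is a superset of s
  f <- tabulate(masks + 1, nbins = total)
  all_masks <- 0:(total - 1)
  for (b in bit) {
    without <- which(bitwAnd(all_masks, b) == 0)
    f[without] <- f[without] + f[without + b]
  }
  sizes <- rowSums(vapply(bit, function(b) {
    bitwAnd(all_masks, b) > 0
  }, logical(total)))

  rows <- list()
  cand <- which(sizes >= 2 & sizes <= config$max_antecedents + 1 & f > 0) - 1
  for (s in cand) {
    c_ab <- f[s + 1]
    member_bits <- bit[bitwAnd(s, bit) > 0]
    for (b in member_bits) {
      a_mask <- s - b
      c_a <- f[a_mask + 1]
      c_b <- f[b + 1]
      sup_ok <- if (config$support_on == "rule") {
        100 * c_ab >= config$min_support_pct * n
      } else {
        100 * c_a >= config$min_support_pct * n
      }
      if (!sup_ok) next
      if (!(100 * c_ab >= config$min_confidence_pct * c_a)) next
      if (!(c_ab * n > config$min_lift * c_a * c_b)) next
      rows[[length(rows) + 1L]] <- list(
        consequent = items[which(bit == b)],
        antecedent = items[bitwAnd(a_mask, bit) > 0],
        count = c_ab, count_antecedent = c_a, count_consequent = c_b
      )
    }
  }
  if (!length(rows)) {
    return(empty_rule_set(tx$stratum, n))
  }
  out <- tibble::tibble(
    consequent = vapply(rows, `[[`, "", "consequent"),
    antecedent = lapply(rows, `[[`, "antecedent"),
    order = vapply(rows, function(r) length(r$antecedent) + 1L, integer(1)),
    count = vapply(rows, function(r) as.integer(r$count), integer(1)),
    count_antecedent = vapply(rows, function(r) {
      as.integer(r$count_antecedent)
    }, integer(1)),
    count_consequent = vapply(rows, function(r) {
      as.integer(r$count_consequent)
    }, integer(1))
  )
  out$support_pct <- 100 * out$count / n
  out$confidence_pct <- 100 * out$count / out$count_antecedent
  out$lift <- out$count * n / (out$count_antecedent * out$count_consequent)
  out <- out[order(out$consequent, vapply(out$antecedent, itemset_key, "")), ]
  out <- out[, c(
    "consequent", "antecedent", "order", "count", "count_antecedent",
    "count_consequent", "support_pct", "confidence_pct", "lift"
  )]
  attr(out, "n") <- n
  attr(out, "stratum") <- tx$stratum
  out
}

#' Write transactions in basket format
#'
#' One line per participant, space-separated item codes; empty transactions
#' become empty lines. The format round-trips through [read_baskets()] and is
#' understood by most rule-mining tools.
#'
#' @param tx A transaction set.
#' @param path Output file path.
#' @export
write_baskets <- function(tx, path) {
  writeLines(vapply(tx$sets, paste, "", collapse = " "), path)
  invisible(path)
}

#' @rdname write_baskets
#' @param stratum Stratum label for the resulting transaction set.
#' @export
read_baskets <- function(path, stratum = NA_character_) {
  lines <- readLines(path)
  sets <- lapply(strsplit(lines, " ", fixed = TRUE), function(x) {
    x[nzchar(x)]
  })
  transactions(sets, stratum = stratum)
}
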