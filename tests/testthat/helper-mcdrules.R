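# Shared fixtures and small generators for the test suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Toy transaction set used throughout the mining tests: five participants
# over items H (hypertension), D (diabetes), S (spondylosis).
toy_transactions <- function() {
  transactions(
    list(c("H", "D"), c("H", "D", "S"), "H", "D", "S"),
    stratum = "toy"
  )
}

# Random transaction sets for property tests: k items, n transactions, each
# item included per transaction with a per-instance random density.
random_transactions <- function(k, n, density_range = c(0.1, 0.6)) {
  items <- sprintf("i%02d", seq_len(k))
  dens <- stats::runif(k, density_range[1], density_range[2])
  sets <- lapply(seq_len(n), function(i) items[stats::runif(k) < dens])
  transactions(sets)
}

random_mining_config <- function() {
  mining_config(
    min_support_pct = stats::runif(1, 1, 25),
    min_confidence_pct = stats::runif(1, 5, 60),
    min_lift = stats::runif(1, 0.8, 1.6),
    max_antecedents = sample(1:5, 1)
  )
}

# Hand-built survey records with explicit grouped-condition columns.
make_records <- function(n = 4,
                         age = rep(60L, n),
                         exercise = rep(TRUE, n),
                         height = rep(1.70, n),
                         weight = rep(65, n),
                         conditions = list()) {
  rec <- tibble::tibble(
    participant_id = sprintf("T%03d", seq_len(n)),
    sex = rep(c("male", "female"), length.out = n),
    age = age,
    education = rep("high", n),
    regular_exercise = exercise,
    height = height,
    weight = weight
  )
  for (col in names(conditions)) rec[[col]] <- conditions[[col]]
  rec
}

# A rule tibble with given antecedents (list), consequents and confidences,
# for post-processing tests.
make_rules <- function(antecedent, consequent, confidence_pct,
                       support_pct = rep(5, length(consequent)),
                       lift = rep(2, length(consequent))) {
  tibble::tibble(
    consequent = consequent,
    antecedent = lapply(antecedent, sort),
    order = lengths(antecedent) + 1L,
    support_pct = support_pct,
    confidence_pct = confidence_pct,
    lift = lift
  )
}

# Monte-Carlo standard errors for sample support / confidence / log-lift of
# a rule, given exact probabilities and the stratum size.
se_support_pct <- function(p_ab, m) 100 * sqrt(p_ab * (1 - p_ab) / m)
se_confidence_pct <- function(p_a, p_ab, m) {
  conf <- p_ab / p_a
  100 * sqrt(conf * (1 - conf) / (m * p_a))
}
se_log_lift <- function(p_a, p_b, p_ab, m) {
  sqrt((1 - p_ab) / (m * p_ab) + (1 - p_a) / (m * p_a) +
    (1 - p_b) / (m * p_b))
}
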