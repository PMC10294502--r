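# End-to-end analysis pipeline: filter -> profile -> stratify -> mine per
# stratum -> dedup -> compare -> descriptives, with optional file outputs and
# a reproducibility manifest.

#' Run the full multimorbidity rule-mining analysis
#'
#' Executes the analysis end to end on supplied survey records or on a
#' freshly simulated synthetic cohort: eligibility filtering, condition
#' profiling, AG/IG stratification, per-stratum Apriori rule mining,
#' symmetric-pair deduplication, stratum comparison (rule diff and
#' disease-frequency table), the participant-characteristics table and the
#' co-occurrence network. When `out_dir` is given, rule tables, comparison
#' tables, network exports and a JSON run manifest are written there; the
#' outputs are byte-identical across runs with the same inputs and seed.
#'
#' @param records Survey records tibble (exactly one of `records` /
#'   `synthetic`).
#' @param synthetic A [synthetic_config()] to simulate records from.
#' @param config A [mining_config()].
#' @param map Grouping map for raw condition codes.
#' @param mcd_includes_obesity Count obesity toward the MCD threshold.
#' @param min_links Co-occurrence threshold for network edges.
#' @param seed Seed used for synthetic generation (overrides the config's).
#' @param out_dir Optional output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return (Invisibly) a list with `profiles`, `rules` (per stratum,
#'   deduplicated), `diff`, `frequency`, `prevalence`, `age_comparison`,
#'   `network` and `manifest`.
#' @export
run_pipeline <- function(records = NULL, synthetic = NULL,
                         config = mining_config(),
                         map = khps_grouping_map(),
                         mcd_includes_obesity = TRUE,
                         min_links = 20,
                         seed = NULL,
                         out_dir = NULL,
                         quiet = FALSE) {
  if (is.null(records) == is.null(synthetic)) {
    stop("supply exactly one of `records` or `synthetic`", call. = FALSE)
  }
  say <- function(...) if (!quiet) message(...)
  if (!is.null(synthetic)) {
    if (!is.null(seed)) synthetic$seed <- seed
    say("simulating cohort (n = ", synthetic$n, ", seed = ",
      synthetic$seed %||% "none", ")")
    records <- simulate_cohort(synthetic)
  }
  n_input <- nrow(records)
  eligible <- filter_eligible(records, quiet = quiet)
  profiles <- build_profiles(eligible,
    map = map,
    mcd_includes_obesity = mcd_includes_obesity
  )
  tx <- profile_transactions(profiles)
  strata <- intersect(c("AG", "IG"), names(tx))
  say(
    "mining rules per stratum (",
    paste(vapply(strata, function(s) {
      paste0(s, " n=", tx[[s]]$n)
    }, ""), collapse = ", "), ")"
  )
  rules <- lapply(tx[strata], function(t) {
    dedup_symmetric_pairs(mine_rules(t, config))
  })
  diff <- frequency <- NULL
  if (all(c("AG", "IG") %in% names(rules))) {
    diff <- diff_rulesets(rules$AG, rules$IG)
    frequency <- frequency_table(rules$AG, rules$IG)
  }
  prevalence <- prevalence_table(profiles)
  age_cmp <- continuous_comparison(profiles, "age")
  network <- network_summary(profiles, min_links = min_links)
  manifest <- list(
    package = "mcdrules",
    version = as.character(utils::packageVersion("mcdrules")),
    seed = if (!is.null(synthetic)) synthetic$seed else NULL,
    thresholds = unclass(config),
    mcd_includes_obesity = mcd_includes_obesity,
    min_links = min_links,
    counts = list(
      input_records = n_input,
      eligible = nrow(eligible),
      dropped = as.list(attr(eligible, "dropped")),
      strata = lapply(tx, `[[`, "n"),
      rules = lapply(rules, nrow)
    )
  )
  result <- list(
    profiles = profiles, rules = rules, diff = diff,
    frequency = frequency, prevalence = prevalence,
    age_comparison = age_cmp, network = network, manifest = manifest
  )
  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir)
    say("outputs written to ", out_dir)
  }
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(result$rules)) {
    write_rules(
      result$rules[[s]],
      file.path(out_dir, paste0("rules_", s, ".csv"))
    )
  }
  if (!is.null(result$frequency)) {
    readr::write_csv(
      result$frequency,
      file.path(out_dir, "frequency_table.csv")
    )
  }
  prev <- result$prevalence
  prev$p_value <- format_pvalue(prev$p_value)
  prev$p_value_corrected <- format_pvalue(prev$p_value_corrected)
  readr::write_csv(prev, file.path(out_dir, "prevalence_table.csv"))
  write_network(result$network,
    edges_csv = file.path(out_dir, "network_edges.csv"),
    graphml = file.path(out_dir, "network.graphml")
  )
  if (!is.null(result$diff)) {
    diff_json <- list(
      labels = result$diff$labels,
      shared = rule_signature(result$diff$shared),
      first_only = rule_signature(result$diff$first_only),
      second_only = rule_signature(result$diff$second_only)
    )
    jsonlite::write_json(diff_json, file.path(out_dir, "rule_diff.json"),
      auto_unbox = FALSE, pretty = TRUE
    )
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null"
  )
  invisible(out_dir)
}
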