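# Descriptive statistics: participant-characteristics table (counts, MCD
# prevalence, chi-square / t-test comparisons) and the disease co-occurrence
# network summary.

#' Participant-characteristics prevalence table
#'
#' For each categorical grouping variable: per-category n, share of the
#' cohort, MCD count and MCD prevalence, with a Pearson chi-square test of
#' MCD status across the categories (computed without continuity correction;
#' for 2x2 tables the Yates-corrected p-value is also reported). A `Total`
#' row gives the overall MCD prevalence.
#'
#' @param profiles Profile tibble from [build_profiles()].
#' @param vars Categorical variables to tabulate (columns of `profiles`).
#' @return Tibble with columns `variable`, `category`, `n`, `pct`, `mcd_n`,
#'   `mcd_pct`, `p_value` (per variable, repeated on its rows) and
#'   `p_value_corrected` (2x2 tables only).
#' @export
prevalence_table <- function(profiles,
                             vars = c(
                               "sex", "age_band", "education", "stratum"
                             )) {
  stopifnot(nrow(profiles) > 0)
  n_all <- nrow(profiles)
  rows <- list()
  for (v in vars) {
    x <- profiles[[v]]
    if (is.null(x)) stop("no column `", v, "` in profiles", call. = FALSE)
    x <- droplevels(as.factor(x))
    empty <- setdiff(levels(as.factor(profiles[[v]])), levels(x))
    if (length(empty)) {
      warning("omitting empty categor(ies) of ", v, ": ",
        paste(empty, collapse = ", "),
        call. = FALSE
      )
    }
    tab <- table(x, factor(profiles$mcd, levels = c(FALSE, TRUE)))
    p <- if (nlevels(x) >= 2) {
      stats::chisq.test(tab, correct = FALSE)$p.value
    } else {
      NA_real_
    }
    p_corr <- if (identical(dim(tab), c(2L, 2L))) {
      stats::chisq.test(tab, correct = TRUE)$p.value
    } else {
      NA_real_
    }
    for (lev in levels(x)) {
      n_cat <- sum(x == lev)
      mcd_n <- sum(profiles$mcd[x == lev])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = v, category = lev, n = n_cat,
        pct = 100 * n_cat / n_all,
        mcd_n = mcd_n, mcd_pct = 100 * mcd_n / n_cat,
        p_value = p, p_value_corrected = p_corr
      )
    }
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(
    variable = "total", category = "Total", n = n_all, pct = 100,
    mcd_n = sum(profiles$mcd), mcd_pct = 100 * mean(profiles$mcd),
    p_value = NA_real_, p_value_corrected = NA_real_
  )
  dplyr::bind_rows(rows)
}

#' Compare a continuous variable between MCD and non-MCD participants
#'
#' Two-sample Welch t-test, the companion to the categorical chi-square rows
#' of [prevalence_table()] (used for age in the characteristics table).
#'
#' @param profiles Profile tibble.
#' @param var Continuous column name, default `"age"`.
#' @return One-row tibble with group means, SDs and the t-test p-value.
#' @export
continuous_comparison <- function(profiles, var = "age") {
  x <- profiles[[var]]
  g <- profiles$mcd
  tt <- stats::t.test(x[g], x[!g])
  tibble::tibble(
    variable = var,
    mean_all = mean(x), sd_all = stats::sd(x),
    mean_mcd = mean(x[g]), sd_mcd = stats::sd(x[g]),
    mean_other = mean(x[!g]), sd_other = stats::sd(x[!g]),
    p_value = tt$p.value
  )
}

#' Format p-values the way clinical tables print them
#'
#' @param p Numeric p-values.
#' @param threshold Values below this print as `"<threshold"`.
#' @return Character vector.
#' @export
format_pvalue <- function(p, threshold = 0.001) {
  ifelse(is.na(p), "-",
    ifelse(p < threshold,
      paste0("<", format(threshold, scientific = FALSE)),
      sprintf("%.3f", p)
    )
  )
}

#' Disease co-occurrence network summary
#'
#' Nodes are diseases, sized by prevalence in the cohort and coloured by the
#' share of the disease's patients who have MCD; edges are pairwise
#' co-occurrence counts, kept only when at least `min_links` participants
#' have both diseases.
#'
#' @param profiles Profile tibble from [build_profiles()].
#' @param min_links Minimum co-occurrence count for an edge (default 20).
#' @param vocabulary Diseases to include as nodes.
#' @return List of class `"comorbidity_network"` with `nodes` (disease,
#'   `n_cases`, `prevalence_pct`, `mcd_pct`), `edges` (`disease_a`,
#'   `disease_b`, `count`) and `min_links`.
#' @export
network_summary <- function(profiles, min_links = 20,
                            vocabulary = condition_vocabulary()) {
  n <- nrow(profiles)
  mat <- vapply(vocabulary, function(d) {
    vapply(profiles$conditions, function(s) d %in% s, logical(1))
  }, logical(n))
  n_cases <- colSums(mat)
  mcd_share <- vapply(seq_along(vocabulary), function(j) {
    if (n_cases[j] == 0) {
      return(NA_real_)
    }
    100 * sum(profiles$mcd[mat[, j]]) / n_cases[j]
  }, numeric(1))
  nodes <- tibble::tibble(
    disease = vocabulary,
    n_cases = as.integer(n_cases),
    prevalence_pct = 100 * n_cases / n,
    mcd_pct = mcd_share
  )
  co <- crossprod(mat)
  pairs <- which(upper.tri(co) & co >= min_links, arr.ind = TRUE)
  edges <- tibble::tibble(
    disease_a = vocabulary[pairs[, 1]],
    disease_b = vocabulary[pairs[, 2]],
    count = as.integer(co[pairs])
  )
  edges <- edges[order(-edges$count, edges$disease_a, edges$disease_b), ]
  structure(
    list(nodes = nodes, edges = edges, min_links = min_links),
    class = "comorbidity_network"
  )
}

#' @export
print.comorbidity_network <- function(x, ...) {
  cat("<comorbidity_network> ", nrow(x$nodes), " diseases, ", nrow(x$edges),
    " edges with co-occurrence >= ", x$min_links, "\n",
    sep = ""
  )
  invisible(x)
}

#' Export a comorbidity network
#'
#' Writes the edge list as CSV and, via igraph, the full attributed graph as
#' GraphML for use in network tools.
#'
#' @param network A [network_summary()] result.
#' @param edges_csv,graphml Output paths (either may be `NULL` to skip).
#' @export
write_network <- function(network, edges_csv = NULL, graphml = NULL) {
  if (!is.null(edges_csv)) {
    readr::write_csv(network$edges, edges_csv)
  }
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      network$edges,
      directed = FALSE,
      vertices = as.data.frame(network$nodes)
    )
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(network)
}
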