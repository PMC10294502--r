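profiles_from_conditions <- function(conditions, stratum = NULL,
                                     sex = NULL, age = NULL) {
  n <- length(conditions)
  tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    sex = sex %||% rep(c("male", "female"), length.out = n),
    age = age %||% rep(60L, n),
    age_band = age_band(age %||% rep(60L, n)),
    education = rep("high", n),
    stratum = stratum %||% rep(c("AG", "IG"), length.out = n),
    conditions = lapply(conditions, sort),
    n_conditions = lengths(conditions),
    mcd = lengths(conditions) >= 2
  )
}

test_that("prevalence rows report n, percentages and MCD share", {
  prof <- profiles_from_conditions(list(
    c("hypertension", "diabetes"), c("hypertension", "spondylosis"),
    "hypertension", character(), character()
  ))
  tab <- suppressWarnings(prevalence_table(prof, vars = "stratum"))
  total <- tab[tab$variable == "total", ]
  expect_equal(total$n, 5)
  expect_equal(total$mcd_n, 2)
  expect_equal(total$mcd_pct, 40)
  expect_equal(sum(tab$n[tab$variable == "stratum"]), 5)

  all_mcd <- profiles_from_conditions(rep(
    list(c("hypertension", "diabetes")), 4
  ))
  tab2 <- suppressWarnings(prevalence_table(all_mcd, vars = "sex"))
  expect_true(all(tab2$mcd_pct == 100))
})

test_that("chi-square matches the direct O/E sum on the reference sex table", {
  # published 2x2: MCD by sex, males 1268/3727, females 2049/4750
  chars <- khps_reference_characteristics()
  sex <- chars[chars$variable == "sex", ]
  tab <- rbind(
    sex$n - sex$mcd_n,
    sex$mcd_n
  )
  # direct Pearson formula as independent oracle
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2_direct <- sum((tab - expected)^2 / expected)
  fit <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(unname(fit$statistic), x2_direct, tolerance = 1e-10)
  expect_lt(fit$p.value, 0.001)
})

test_that("chi-square oracle identity holds on random 2xk tables", {
  set.seed(31)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    tab <- matrix(rpois(2 * k, lambda = 40) + 5, nrow = 2)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    x2 <- sum((tab - expected)^2 / expected)
    expect_equal(
      unname(stats::chisq.test(tab, correct = FALSE)$statistic),
      x2,
      tolerance = 1e-10
    )
  }
})

test_that("p-values format in the clinical style", {
  expect_equal(format_pvalue(c(0.0004, 0.034, NA)), c("<0.001", "0.034", "-"))
})

test_that("continuous comparison runs a two-sample t-test on age", {
  prof <- profiles_from_conditions(
    rep(list(c("a", "b"), character()), 10),
    age = rep(c(70L, 55L), 10) + rep(0:4, each = 4)
  )
  cmp <- continuous_comparison(prof, "age")
  expect_equal(cmp$mean_mcd, mean(prof$age[prof$mcd]))
  expect_gt(cmp$mean_mcd - cmp$mean_other, 10)
  expect_lt(cmp$p_value, 0.001)
})

test_that("network edges respect the minimum-link threshold", {
  # diseases never co-occur: no edges
  lonely <- profiles_from_conditions(rep(
    list("hypertension", "diabetes"), 30
  ))
  net0 <- network_summary(lonely, min_links = 1)
  expect_equal(nrow(net0$edges), 0)

  # a pair co-occurring in exactly 19 participants misses threshold 20
  co19 <- profiles_from_conditions(c(
    rep(list(c("hypertension", "diabetes")), 19),
    rep(list(character()), 10)
  ))
  expect_equal(nrow(network_summary(co19, min_links = 20)$edges), 0)
  at20 <- profiles_from_conditions(c(
    rep(list(c("hypertension", "diabetes")), 20),
    rep(list(character()), 10)
  ))
  net <- network_summary(at20, min_links = 20)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$count, 20L)
})

test_that("a planted co-occurrence count is recovered exactly", {
  conditions <- c(
    rep(list(c("gonarthrosis", "spondylosis")), 500),
    rep(list("gonarthrosis"), 200),
    rep(list(character()), 4300)
  )
  net <- network_summary(profiles_from_conditions(conditions))
  edge <- net$edges[net$edges$disease_a == "gonarthrosis" |
    net$edges$disease_b == "gonarthrosis", ]
  expect_equal(edge$count, 500L)
  gon <- net$nodes[net$nodes$disease == "gonarthrosis", ]
  expect_equal(gon$n_cases, 700L)
  expect_equal(gon$prevalence_pct, 100 * 700 / 5000)
  # node MCD share: only the 500 comorbid patients have MCD
  expect_equal(gon$mcd_pct, 100 * 500 / 700)
})

test_that("network node prevalence agrees with the prevalence table", {
  cfg <- synthetic_config(n = 800, seed = 9)
  prof <- build_profiles(simulate_cohort(cfg))
  net <- network_summary(prof)
  direct <- vapply(net$nodes$disease, function(d) {
    100 * mean(vapply(prof$conditions, function(s) d %in% s, logical(1)))
  }, numeric(1))
  expect_equal(net$nodes$prevalence_pct, unname(direct))
})

test_that("network export writes GraphML and an edge list", {
  cfg <- synthetic_config(n = 500, seed = 12)
  prof <- build_profiles(simulate_cohort(cfg))
  net <- network_summary(prof, min_links = 5)
  csv <- withr::local_tempfile(fileext = ".csv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, edges_csv = csv, graphml = gml)
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)),
    nrow(net$edges))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
})
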