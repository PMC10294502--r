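test_that("frequent itemsets on the toy set match exhaustive enumeration", {
  # 5 transactions over {H, D, S}; at 40% support the frequent collection,
  # worked out by enumerating all 7 itemsets, is exactly
  # {H}:60, {D}:60, {S}:40, {H,D}:40
  fi <- mine_frequent_itemsets(toy_transactions(), min_support_pct = 40)
  got <- stats::setNames(
    fi$support_pct,
    vapply(fi$items, paste, "", collapse = "+")
  )
  expect_mapequal(got, c(H = 60, D = 60, S = 40, "D+H" = 40))
})

test_that("support threshold edge cases behave", {
  tx <- toy_transactions()
  expect_equal(nrow(mine_frequent_itemsets(tx, min_support_pct = 100.1)), 0)
  one <- transactions(list("H"))
  fi <- mine_frequent_itemsets(one, min_support_pct = 50)
  expect_equal(fi$support_pct, 100)
  expect_error(
    mine_frequent_itemsets(transactions(list()), 10),
    "empty transaction"
  )
  expect_error(mine_frequent_itemsets(tx, 10, max_size = 0), "max_size")
})

test_that("rule thresholds are applied as computed: D -> H fails lift 1.5", {
  tx <- toy_transactions()
  # hand computation: support 2/5 = 40, confidence 2/3 = 66.67,
  # lift (2/5)/((3/5)(3/5)) = 1.111 -- below the strict 1.5 lift cut
  strict <- mine_rules(tx, mining_config(
    min_support_pct = 40, min_confidence_pct = 20, min_lift = 1.5
  ))
  expect_equal(nrow(strict), 0)
  loose <- mine_rules(tx, mining_config(
    min_support_pct = 40, min_confidence_pct = 20, min_lift = 1.0
  ))
  dh <- loose[loose$consequent == "H", ]
  expect_equal(dh$support_pct, 40)
  expect_equal(dh$confidence_pct, 200 / 3, tolerance = 1e-12)
  expect_equal(dh$lift, (2 / 5) / (3 / 5 * 3 / 5), tolerance = 1e-12)
})

test_that("a lift threshold equal to the computed lift excludes the rule", {
  # A and B always together in 2 of 4 transactions: lift exactly 2
  tx <- transactions(list(c("A", "B"), c("A", "B"), "C", "D"))
  at <- mine_rules(tx, mining_config(
    min_support_pct = 25, min_confidence_pct = 20, min_lift = 2
  ))
  expect_equal(nrow(at), 0) # strict inequality
  below <- mine_rules(tx, mining_config(
    min_support_pct = 25, min_confidence_pct = 20, min_lift = 1.99
  ))
  expect_equal(sort(rule_signature(below)), c("A => B", "B => A"))
})

test_that("perfect implication gives confidence 100 and lift 1/P(B)", {
  tx <- transactions(list(
    c("A", "B"), c("A", "B"), "B", "B", "C"
  ))
  rules <- mine_rules(tx, mining_config(
    min_support_pct = 10, min_confidence_pct = 10, min_lift = 1.0
  ))
  ab <- rules[rules$consequent == "B" &
    vapply(rules$antecedent, identical, TRUE, "A"), ]
  expect_equal(ab$confidence_pct, 100)
  expect_equal(ab$lift, 1 / (4 / 5), tolerance = 1e-12)
})

test_that("metric identities hold exactly before rounding", {
  set.seed(101)
  for (i in 1:10) {
    tx <- random_transactions(sample(4:8, 1), sample(30:120, 1))
    cfg <- random_mining_config()
    rules <- mine_rules(tx, cfg)
    if (!nrow(rules)) next
    n <- attr(rules, "n")
    # confidence * P(A) = support; lift * P(B) * 100 = confidence
    expect_equal(
      rules$confidence_pct * rules$count_antecedent / n,
      rules$support_pct,
      tolerance = 1e-12
    )
    expect_equal(
      rules$lift * rules$count_consequent / n * 100,
      rules$confidence_pct,
      tolerance = 1e-12
    )
    # anti-monotonicity of support
    expect_true(all(rules$count <= rules$count_antecedent))
    expect_true(all(rules$count <= rules$count_consequent))
    # thresholds respected
    expect_true(all(rules$support_pct >= cfg$min_support_pct))
    expect_true(all(rules$confidence_pct >= cfg$min_confidence_pct))
    expect_true(all(rules$lift > cfg$min_lift))
    expect_true(all(lengths(rules$antecedent) <= cfg$max_antecedents))
  }
})

test_that("every subset of a frequent itemset is frequent (downward closure)", {
  set.seed(202)
  for (i in 1:5) {
    tx <- random_transactions(sample(5:9, 1), sample(40:150, 1))
    thr <- stats::runif(1, 2, 20)
    fi <- mine_frequent_itemsets(tx, thr)
    keys <- vapply(fi$items, paste, "", collapse = "+")
    for (j in seq_len(nrow(fi))) {
      items <- fi$items[[j]]
      if (length(items) < 2) next
      for (drop in seq_along(items)) {
        expect_true(paste(items[-drop], collapse = "+") %in% keys)
      }
    }
  }
})

test_that("Apriori agrees with brute force on random instances", {
  set.seed(303)
  for (i in 1:25) {
    tx <- random_transactions(sample(3:10, 1), sample(10:200, 1))
    cfg <- random_mining_config()
    a <- mine_rules(tx, cfg)
    b <- brute_force_rules(tx, cfg)
    expect_identical(rule_signature(a), rule_signature(b))
    expect_equal(a$support_pct, b$support_pct, tolerance = 1e-12)
    expect_equal(a$confidence_pct, b$confidence_pct, tolerance = 1e-12)
    expect_equal(a$lift, b$lift, tolerance = 1e-12)
  }
})

test_that("both paths also agree in the antecedent-support dialect", {
  set.seed(404)
  for (i in 1:10) {
    tx <- random_transactions(sample(4:8, 1), sample(20:120, 1))
    cfg <- mining_config(
      min_support_pct = stats::runif(1, 2, 20),
      min_confidence_pct = stats::runif(1, 5, 40),
      min_lift = stats::runif(1, 0.8, 1.4),
      max_antecedents = sample(1:4, 1),
      support_on = "antecedent"
    )
    expect_identical(
      rule_signature(mine_rules(tx, cfg)),
      rule_signature(brute_force_rules(tx, cfg))
    )
  }
})

test_that("brute force refuses oversized vocabularies, handles empty ones", {
  big <- transactions(list(sprintf("i%02d", 1:19)))
  expect_error(brute_force_rules(big), "18 items")
  empty_items <- transactions(list(character(), character()))
  expect_equal(nrow(brute_force_rules(empty_items)), 0)
})

test_that("baskets round-trip through the basket file format", {
  tx <- toy_transactions()
  path <- withr::local_tempfile(fileext = ".basket")
  write_baskets(tx, path)
  back <- read_baskets(path, stratum = "toy")
  expect_equal(back$sets, tx$sets)
  expect_equal(back$n, tx$n)
})
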