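test_that("BMI follows weight/height^2 and rejects impossible records", {
  expect_equal(compute_bmi(70, 1.75), 22.857, tolerance = 1e-4)
  expect_equal(compute_bmi(28, 1.0), 28.0)
  expect_equal(compute_bmi(90, 1.70), 31.142, tolerance = 1e-4)
  expect_equal(
    compute_bmi(c(70, 90), c(1.75, 1.70)),
    c(70 / 1.75^2, 90 / 1.70^2)
  )
  expect_error(
    compute_bmi(0, 1.7, participant_id = "P9"),
    "invalid record.*P9"
  )
  expect_error(compute_bmi(70, -1), "invalid record")
})

test_that("obesity is a strict BMI > 28 cut", {
  expect_true(derive_obesity(31.14))
  expect_false(derive_obesity(28.0))
  expect_false(derive_obesity(22.86))
  expect_equal(derive_obesity(c(27.99, 28.01)), c(FALSE, TRUE))
})

test_that("raw condition codes collapse onto the 14 grouped categories", {
  map <- khps_grouping_map()
  expect_length(map, 30)
  expect_setequal(unique(unname(map)), condition_vocabulary(FALSE))
  expect_equal(
    group_conditions("chronic_hepatitis", map),
    "chronic_liver_disease"
  )
  expect_equal(
    group_conditions(c("cerebral_hemorrhage", "cerebral_infarction"), map),
    "cerebrovascular_disease"
  )
  expect_equal(group_conditions(character(), map), character())
  expect_error(group_conditions("not_a_code", map), "unknown condition")
  # idempotent on already-grouped codes, and never grows the set
  for (set in list(
    c("hypertension", "diabetes"),
    c("gastric_cancer", "lung_cancer", "hypertension")
  )) {
    once <- group_conditions(set, map)
    expect_identical(group_conditions(once, map), once)
    expect_lte(length(once), length(set))
  }
})

test_that("profiles combine grouped conditions, obesity, MCD and stratum", {
  rec <- make_records(
    n = 3,
    exercise = c(TRUE, TRUE, FALSE),
    weight = c(65, 65, 90),
    height = c(1.70, 1.70, 1.70),
    conditions = list(
      hypertension = c(1L, 1L, 0L),
      diabetes = c(1L, 0L, 0L)
    )
  )
  prof <- build_profiles(rec)
  expect_equal(prof$conditions[[1]], c("diabetes", "hypertension"))
  expect_true(prof$mcd[1])
  expect_equal(prof$stratum[1], "AG")
  expect_false(prof$mcd[2]) # single condition
  # BMI 31.1: obesity only, mcd FALSE, inactive stratum
  expect_equal(prof$conditions[[3]], "obesity")
  expect_false(prof$mcd[3])
  expect_equal(prof$stratum[3], "IG")
})

test_that("the MCD counting convention switch excludes obesity", {
  rec <- make_records(
    n = 1, weight = 90, height = 1.70,
    conditions = list(hypertension = 1L)
  )
  expect_true(build_profiles(rec)$mcd)
  expect_false(build_profiles(rec, mcd_includes_obesity = FALSE)$mcd)
})

test_that("eligibility keeps ages 46+ with complete data and logs drops", {
  rec <- make_records(n = 3, age = c(45L, 46L, 80L))
  kept <- filter_eligible(rec, quiet = TRUE)
  expect_equal(kept$age, c(46L, 80L))
  expect_equal(attr(kept, "dropped")[["age"]], 1L)

  rec$height[3] <- NA
  kept2 <- filter_eligible(rec, quiet = TRUE)
  expect_equal(kept2$age, 46L)
  expect_equal(attr(kept2, "dropped")[["incomplete"]], 1L)

  empty <- filter_eligible(make_records(n = 0), quiet = TRUE)
  expect_equal(nrow(empty), 0L)
  expect_message(filter_eligible(rec), "eligible")
})

test_that("stratification partitions the eligible cohort", {
  cfg <- synthetic_config(n = 600, seed = 5)
  prof <- build_profiles(filter_eligible(simulate_cohort(cfg), quiet = TRUE))
  expect_equal(sum(prof$stratum == "AG") + sum(prof$stratum == "IG"),
    nrow(prof))
  expect_true(all(prof$stratum %in% c("AG", "IG")))
})

test_that("adding a condition never flips MCD from true to false", {
  rec <- make_records(
    n = 3,
    conditions = list(
      hypertension = c(1L, 1L, 0L),
      diabetes = c(1L, 0L, 0L)
    )
  )
  before <- build_profiles(rec)$mcd
  rec$spondylosis <- 1L
  after <- build_profiles(rec)$mcd
  expect_false(any(before & !after))
})

test_that("an all-zero-marginal synthetic cohort is disease-free", {
  marg <- stats::setNames(
    rep(0, length(condition_vocabulary())),
    condition_vocabulary()
  )
  cfg <- synthetic_config(
    n = 300, seed = 1, marginal_prevalence = marg,
    planted_associations = list()
  )
  prof <- build_profiles(simulate_cohort(cfg))
  expect_true(all(lengths(prof$conditions) == 0))
  expect_false(any(prof$mcd))
})

test_that("cohort files round-trip, including cm heights and column maps", {
  rec <- make_records(n = 2, conditions = list(hypertension = c(1L, 0L)))
  path <- withr::local_tempfile(fileext = ".csv")
  out <- rec
  out$height <- out$height * 100
  names(out)[names(out) == "height"] <- "height_cm"
  readr::write_csv(out, path)
  back <- read_cohort(path,
    columns = c(height = "height_cm"),
    height_unit = "cm"
  )
  expect_equal(back$height, rec$height)
  expect_equal(back$regular_exercise, rec$regular_exercise)
  expect_error(read_cohort(path), "height")
})
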