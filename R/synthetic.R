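# Synthetic cohort generation. Disease indicators follow a sequential
# logistic model over a fixed conditioning order: each disease's baseline
# log-odds is adjusted so its marginal prevalence hits the configured target,
# and planted associations add a log-odds boost to the last member of the
# association (in conditioning order) whenever all its other members are
# already present. This construction gives exact, cheaply enumerable joint
# probabilities for planted itemsets, used as ground truth in recovery tests.

#' Default marginal disease prevalences for synthetic cohorts
#'
#' Hypertension (40.2%), spondylosis (18.7%) and diabetes (17.6%) use the
#' reported cohort prevalences; the remaining conditions use round
#' placeholder values of plausible magnitude for a 46+ health-panel
#' population.
#'
#' @return Named numeric vector over the 15-condition vocabulary.
#' @export
default_marginals <- function() {
  c(
    hypertension = 0.402,
    diabetes = 0.176,
    chronic_liver_disease = 0.03,
    gonarthrosis = 0.15,
    arthritis = 0.10,
    spondylosis = 0.187,
    cancer = 0.05,
    cardiovascular_disease = 0.05,
    cerebrovascular_disease = 0.04,
    chronic_respiratory_disease = 0.05,
    thyroid_disease = 0.06,
    depression = 0.04,
    alzheimers_disease = 0.03,
    chronic_renal_failure = 0.02,
    obesity = 0.07
  )
}

#' Default planted pairwise associations
#'
#' A small set of clinically motivated disease pairs: the metabolic cluster
#' (hypertension-diabetes), the musculoskeletal cluster
#' (gonarthrosis-spondylosis, arthritis-gonarthrosis,
#' obesity-gonarthrosis) in both strata, and two links planted only in the
#' inactive stratum (cardiovascular disease-hypertension,
#' depression-hypertension) so the default cohort shows more structure in
#' the IG, as the study population does.
#'
#' @return List of planted associations (`items`, `log_or`, `strata`).
#' @export
default_planted_associations <- function() {
  list(
    list(
      items = c("hypertension", "diabetes"), log_or = 1.0,
      strata = c("AG", "IG")
    ),
    list(
      items = c("gonarthrosis", "spondylosis"), log_or = 1.1,
      strata = c("AG", "IG")
    ),
    list(
      items = c("arthritis", "gonarthrosis"), log_or = 0.9,
      strata = c("AG", "IG")
    ),
    list(
      items = c("gonarthrosis", "obesity"), log_or = 0.8,
      strata = c("AG", "IG")
    ),
    list(
      items = c("hypertension", "cardiovascular_disease"), log_or = 0.9,
      strata = "IG"
    ),
    list(
      items = c("hypertension", "depression"), log_or = 0.7,
      strata = "IG"
    )
  )
}

#' Configuration for synthetic cohort generation
#'
#' Defaults emulate the study cohort: 8477 participants aged over 45, 55.6%
#' with regular exercise habits, 44% male, the reported age-band and
#' education distributions, and disease marginals from
#' [default_marginals()].
#'
#' @param n Cohort size.
#' @param seed Integer seed; `simulate_cohort()` uses it when set.
#' @param exercise_prob Probability of regular exercise (AG membership).
#' @param marginal_prevalence Named per-disease marginal probabilities over
#'   the 15-condition vocabulary.
#' @param planted_associations List of associations, each a list with
#'   `items` (two or more condition codes), `log_or` (log-odds boost applied
#'   to the last item in conditioning order when all the others are present)
#'   and `strata` (subset of `c("AG", "IG")`).
#' @param sex_male_prob Probability of male sex.
#' @param age_band_probs Named probabilities over the four age bands.
#' @param education_probs Named probabilities over the education levels.
#' @param bmi_meanlog,bmi_sdlog Lognormal BMI parameters; BMI is drawn from
#'   the lognormal truncated above/below 28 kg/m^2 according to the drawn
#'   obesity indicator.
#' @param conditioning_order Order in which diseases are drawn; part of the
#'   model definition.
#' @return List of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n = 8477,
                             seed = NULL,
                             exercise_prob = 0.556,
                             marginal_prevalence = default_marginals(),
                             planted_associations =
                               default_planted_associations(),
                             sex_male_prob = 0.44,
                             age_band_probs = c(
                               "46-55" = 0.217, "56-65" = 0.297,
                               "66-75" = 0.292, ">75" = 0.195
                             ),
                             education_probs = c(
                               "elementary_or_below" = 0.297,
                               "middle" = 0.183,
                               "high" = 0.328,
                               "university_or_above" = 0.191
                             ),
                             bmi_meanlog = log(23.8),
                             bmi_sdlog = 0.13,
                             conditioning_order = condition_vocabulary()) {
  vocab <- condition_vocabulary()
  stopifnot(n >= 1)
  missing_marg <- setdiff(vocab, names(marginal_prevalence))
  if (length(missing_marg)) {
    stop("marginal_prevalence lacks: ", paste(missing_marg, collapse = ", "),
      call. = FALSE
    )
  }
  probs <- c(
    exercise_prob, sex_male_prob, marginal_prevalence,
    age_band_probs, education_probs
  )
  stopifnot(all(probs >= 0 & probs <= 1))
  stopifnot(setequal(conditioning_order, vocab))
  for (p in planted_associations) {
    bad <- setdiff(p$items, vocab)
    if (length(bad)) {
      stop("planted association references unknown disease(s): ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    stopifnot(
      length(p$items) >= 2, is.finite(p$log_or),
      all(p$strata %in% c("AG", "IG"))
    )
  }
  structure(
    list(
      n = n, seed = seed, exercise_prob = exercise_prob,
      marginal_prevalence = marginal_prevalence[vocab],
      planted_associations = planted_associations,
      sex_male_prob = sex_male_prob,
      age_band_probs = age_band_probs / sum(age_band_probs),
      education_probs = education_probs / sum(education_probs),
      bmi_meanlog = bmi_meanlog, bmi_sdlog = bmi_sdlog,
      conditioning_order = conditioning_order
    ),
    class = "synthetic_config"
  )
}

# Per-stratum model: marginal-preserving baseline log-odds and the exact
# joint distribution over all diseases involved in planted associations.
stratum_model <- function(cfg, stratum) {
  ord <- cfg$conditioning_order
  plants <- Filter(
    function(p) stratum %in% p$strata,
    cfg$planted_associations
  )
  involved <- intersect(ord, unique(unlist(lapply(plants, `[[`, "items"))))
  marg <- cfg$marginal_prevalence
  alpha <- stats::qlogis(marg[ord])
  # plants keyed by the member drawn last, which receives the boost
  targets <- stats::setNames(
    lapply(ord, function(j) {
      Filter(function(p) {
        utils::tail(intersect(ord, p$items), 1) == j
      }, plants)
    }),
    ord
  )
  configs <- matrix(numeric(0), nrow = 1, ncol = 0)
  probs <- 1
  for (j in involved) {
    boost <- numeric(nrow(configs))
    for (p in targets[[j]]) {
      others <- setdiff(p$items, j)
      present <- if (length(others)) {
        rowSums(configs[, others, drop = FALSE]) == length(others)
      } else {
        rep(TRUE, nrow(configs))
      }
      boost <- boost + p$log_or * present
    }
    if (any(boost != 0) && marg[[j]] > 0 && marg[[j]] < 1) {
      fn <- function(a) sum(probs * stats::plogis(a + boost)) - marg[[j]]
      alpha[j] <- stats::uniroot(fn, c(-35, 35), tol = 1e-12)$root
    }
    pj <- stats::plogis(alpha[[j]] + boost)
    new_col_1 <- cbind(configs, 1)
    new_col_0 <- cbind(configs, 0)
    colnames(new_col_1) <- colnames(new_col_0) <- c(colnames(configs), j)
    configs <- rbind(new_col_1, new_col_0)
    probs <- c(probs * pj, probs * (1 - pj))
  }
  list(
    stratum = stratum, alpha = alpha, targets = targets,
    involved = involved, configs = configs, probs = probs
  )
}

joint_probability <- function(model, items, marg) {
  in_model <- intersect(items, model$involved)
  outside <- setdiff(items, model$involved)
  p_in <- if (length(in_model)) {
    sel <- rowSums(model$configs[, in_model, drop = FALSE] == 1) ==
      length(in_model)
    sum(model$probs[sel])
  } else {
    1
  }
  p_in * prod(marg[outside])
}

#' Simulate a survey cohort
#'
#' Draws exercise stratum, demographics and BMI, then disease indicators
#' from the sequential logistic model (see [synthetic_config()]). The
#' emitted table has the delimited-cohort layout that [build_profiles()]
#' consumes: demographics plus one 0/1 column per grouped condition; obesity
#' is encoded through height and weight (BMI above or below 28) rather than
#' as a column, exactly as in real survey data.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed; defaults to `cfg$seed`. The draw is
#'   deterministic given config and seed.
#' @return Tibble of survey records.
#' @export
simulate_cohort <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n
  exercise <- stats::runif(n) < cfg$exercise_prob
  stratum <- ifelse(exercise, "AG", "IG")
  sex <- ifelse(stats::runif(n) < cfg$sex_male_prob, "male", "female")
  band <- sample(names(cfg$age_band_probs), n,
    replace = TRUE,
    prob = cfg$age_band_probs
  )
  band_range <- list(
    "46-55" = 46:55, "56-65" = 56:65, "66-75" = 66:75, ">75" = 76:95
  )
  age <- vapply(band, function(b) {
    sample(band_range[[b]], 1)
  }, integer(1))
  education <- sample(names(cfg$education_probs), n,
    replace = TRUE,
    prob = cfg$education_probs
  )

  models <- list(AG = stratum_model(cfg, "AG"), IG = stratum_model(cfg, "IG"))
  ord <- cfg$conditioning_order
  d <- matrix(0L,
    nrow = n, ncol = length(ord),
    dimnames = list(NULL, ord)
  )
  for (j in ord) {
    lp <- numeric(n)
    for (st in c("AG", "IG")) {
      idx <- which(stratum == st)
      if (!length(idx)) next
      m <- models[[st]]
      lpj <- rep(m$alpha[[j]], length(idx))
      for (p in m$targets[[j]]) {
        others <- setdiff(p$items, j)
        present <- rowSums(d[idx, others, drop = FALSE] == 1L) ==
          length(others)
        lpj <- lpj + p$log_or * present
      }
      lp[idx] <- lpj
    }
    d[, j] <- as.integer(stats::runif(n) < stats::plogis(lp))
  }

  obese <- d[, "obesity"] == 1L
  q28 <- stats::plnorm(28, cfg$bmi_meanlog, cfg$bmi_sdlog)
  u <- stats::runif(n, min = 0.001, max = 0.999)
  bmi <- ifelse(obese,
    stats::qlnorm(q28 + u * (1 - q28), cfg$bmi_meanlog, cfg$bmi_sdlog),
    stats::qlnorm(u * q28, cfg$bmi_meanlog, cfg$bmi_sdlog)
  )
  height <- stats::rnorm(n, ifelse(sex == "male", 1.70, 1.58), 0.06)
  height <- pmax(height, 1.3)
  weight <- bmi * height^2

  grouped <- setdiff(ord, "obesity")
  out <- tibble::tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    sex = sex,
    age = as.integer(age),
    education = education,
    regular_exercise = exercise,
    height = round(height, 3),
    weight = round(weight, 2)
  )
  for (g in grouped) out[[g]] <- d[, g]
  out
}

#' Exact expected rule metrics under a synthetic configuration
#'
#' Computes, by exact enumeration of the sequential logistic model's joint
#' distribution over the involved diseases, the implied P(A), P(B), P(A,B)
#' per stratum and hence the expected support, confidence and lift of a
#' rule A -> B. Diseases outside every planted association are independent,
#' so their marginals factor out.
#'
#' @param cfg A [synthetic_config()].
#' @param antecedent Character vector of antecedent condition codes.
#' @param consequent Single consequent condition code.
#' @return Tibble with one row per stratum: `p_antecedent`, `p_consequent`,
#'   `p_joint`, `support_pct`, `confidence_pct`, `lift`.
#' @export
expected_rule_metrics <- function(cfg, antecedent, consequent) {
  stopifnot(length(consequent) == 1, !consequent %in% antecedent)
  marg <- cfg$marginal_prevalence
  rows <- lapply(c("AG", "IG"), function(st) {
    m <- stratum_model(cfg, st)
    p_a <- joint_probability(m, antecedent, marg)
    p_b <- joint_probability(m, consequent, marg)
    p_ab <- joint_probability(m, c(antecedent, consequent), marg)
    tibble::tibble(
      stratum = st,
      p_antecedent = p_a, p_consequent = p_b, p_joint = p_ab,
      support_pct = 100 * p_ab,
      confidence_pct = 100 * p_ab / p_a,
      lift = p_ab / (p_a * p_b)
    )
  })
  dplyr::bind_rows(rows)
}

#' Ground truth for every planted association
#'
#' For each planted association and each single-item consequent split of its
#' item set, the exact expected support, confidence and lift in both strata
#' (see [expected_rule_metrics()]). In a stratum where a plant does not
#' apply, its items are independent and the expected lift is 1.
#'
#' @param cfg A [synthetic_config()].
#' @return Tibble with one row per (plant, consequent split, stratum).
#' @export
planted_rule_truth <- function(cfg) {
  rows <- list()
  for (i in seq_along(cfg$planted_associations)) {
    p <- cfg$planted_associations[[i]]
    for (b in p$items) {
      a <- setdiff(p$items, b)
      em <- expected_rule_metrics(cfg, a, b)
      em$plant <- i
      em$antecedent <- paste(sort(a), collapse = ";")
      em$consequent <- b
      em$planted_in <- paste(p$strata, collapse = "+")
      rows[[length(rows) + 1L]] <- em
    }
  }
  out <- dplyr::bind_rows(rows)
  out[, c(
    "plant", "antecedent", "consequent", "planted_in", "stratum",
    "p_antecedent", "p_consequent", "p_joint", "support_pct",
    "confidence_pct", "lift"
  )]
}
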