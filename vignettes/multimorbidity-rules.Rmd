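---
title: "Mining multimorbidity patterns by exercise stratum with mcdrules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining multimorbidity patterns by exercise stratum with mcdrules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdrules)
```

## The problem and the model

Multiple chronic diseases (MCD) — two or more chronic conditions in one
person — cluster in patterns, and the patterns differ between people with
and without regular exercise habits. `mcdrules` treats each participant's
set of present conditions as a *transaction* and mines association rules
A → B within each exercise stratum separately, so that differences between
the mined rule sets can be read as differences in comorbidity structure.

For a rule with antecedent set A and single consequent condition B,
estimated on the n participants of one stratum:

* **support** = 100 · P̂(A, B), the share of the stratum with every condition
  in A and B;
* **confidence** = 100 · P̂(A, B) / P̂(A), the share of patients with A who
  also have B;
* **lift** = confidence / (100 · P̂(B)), the factor by which A raises the
  probability of B over its base prevalence. Lift 1 means independence;
  because base prevalences differ enormously between conditions (40 % for
  hypertension, ~2 % for chronic renal failure), lift is the primary
  evaluation scale here.

Frequent itemsets are found with a level-wise Apriori search: size-k
frequent itemsets sharing a (k−1)-prefix are joined into candidates,
candidates with any infrequent subset are pruned (downward closure), and
survivors are counted. Every frequent itemset of size ≥ 2 is then split
into each single-consequent rule and filtered on the thresholds.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_support_pct` | 1.5 | minimum rule (joint) support, % of stratum, inclusive |
| `min_confidence_pct` | 20 | minimum confidence, %, inclusive |
| `min_lift` | 1.5 | lift threshold, **strict** (rules need lift > 1.5) |
| `max_antecedents` | 5 | largest antecedent set |
| `support_on` | `"rule"` | what the support threshold applies to |

The defaults are the analysis settings used with the ~8,500-participant
survey cohort; at that size, 1.5 % support corresponds to ≥ ~60
participants per rule, which keeps confidence estimates stable. The
support threshold applies to the *rule* (joint) support by default — the
smallest supports in the reference tables are 1.51–1.52 %, consistent with
that reading. Some mining tools instead threshold the *antecedent* support;
`support_on = "antecedent"` reproduces that dialect (internally the itemset
enumeration then descends to `min_support × min_confidence / 100`, the
lowest joint support any passing rule can have).

Consequents are single conditions; multi-item consequents are out of scope
(none appear in the reference analysis).

### Duplicate removal and rule order

Two-variable rules come in symmetric pairs — (A → B) and (B → A) describe
the same co-occurrence — so `dedup_symmetric_pairs()` keeps only the
higher-confidence direction of each pair. Ties are broken toward the
consequent that sorts first, which makes the result invariant to input
order. The rule is deliberately restricted to order 2: the reference
tables retain both members of order-3 symmetric pairs (e.g. both
{diabetes, spondylosis} → gonarthrosis and {gonarthrosis, diabetes} →
spondylosis), so the published deduplication is demonstrably not applied
at higher orders.

A rule's *order* is the number of distinct conditions involved
(antecedent size + 1): a "four-variable" rule has three antecedents.

### Comparing strata

`diff_rulesets()` matches rules across strata by signature (antecedent set
+ consequent), ignoring metrics. `frequency_table()` counts, per disease,
how often it appears as a consequent and inside an antecedent in each rule
set, and reports the frequency-increase statistic 100·(B − A)/A on the
totals (rounded to the nearest integer; undefined — printed "-" — when the
baseline is zero). Counting is naive: one increment per rule row. For the
reference tables this reproduces the published comparison row for
hypertension and cardiovascular disease and every inactive-group column,
but for three diseases the published active-group antecedent counts are
lower than a direct recount of the active-group rule table; the published
counting convention is not described, so the package does not try to
reverse-engineer it and instead ships the published totals as a separate
fixture (`khps_reference_counts()`).

## Cohort preparation choices

* **Eligibility**: "aged over 45" is implemented as age ≥ 46 in integer
  years, matching the lowest reported age band (46–55). Records with
  missing exercise, anthropometric or condition data are dropped listwise
  and counted, never silently.
* **Obesity**: BMI = weight(kg)/height²(m); obesity is BMI **strictly**
  greater than 28, the cut above which obesity-related morbidity rises
  three- to four-fold in adults. Files with centimetre heights declare it
  at read time (`read_cohort(..., height_unit = "cm")`).
* **MCD convention**: the analysis screens 15 chronic conditions
  *including* obesity, so by default all 15 count toward the ≥ 2
  threshold. Whether the published MCD counts include obesity is not
  stated, so `mcd_includes_obesity = FALSE` switches to counting only the
  14 grouped survey conditions; both conventions are first-class.
* **Exercise coding**: any affirmative answer to the regular-exercise
  question (walking included) puts a participant in the active group (AG);
  everything else is inactive (IG). Stratification is a partition.
* **Grouping**: the 30 raw survey condition codes collapse onto 14 grouped
  diseases via an editable YAML resource
  (`inst/extdata/khps_grouping.yaml`); the map must stay total and
  surjective, and grouping is idempotent so cohorts already coded at the
  grouped level pass through unchanged.

## The synthetic-data generator

The restricted survey microdata cannot be shipped, so
`synthetic_config()` + `simulate_cohort()` generate cohorts with the
statistical structure the analysis assumes: n = 8,477 participants aged
over 45, 55.6 % with regular exercise habits, 44 % male, the reported
age-band and education distributions, and 15 binary conditions.

Disease indicators follow a **sequential logistic model**. Diseases are
drawn in a fixed conditioning order (part of the configuration). Disease j
gets linear predictor

> logit P(d_j = 1) = α_j + Σ boosts,

where a planted association {items, log-OR, strata} contributes its log-OR
to the *last* of its items in conditioning order, in the strata where it
applies, whenever all its other items are already present. The baseline
α_j is solved (by exact enumeration of the predecessors' joint
distribution and `uniroot`) so the configured marginal prevalence is
preserved exactly — boosting a pair does not inflate either disease's
prevalence. This construction was chosen over a Gaussian copula because it
makes the implied joint distribution of all involved diseases exactly
enumerable: `planted_rule_truth()` returns closed-form expected
support/confidence/lift per stratum, which the recovery tests compare
against mined values.

Defaults: the three reported prevalences (hypertension 40.2 %, spondylosis
18.7 %, diabetes 17.6 %) are used as-is; the other twelve marginals are
round placeholder values of plausible magnitude for this age group — they
are configuration defaults, not survey estimates. The default plants are a
small set of clinically motivated pairs: hypertension–diabetes,
gonarthrosis–spondylosis, arthritis–gonarthrosis and
obesity–gonarthrosis in both strata, plus
cardiovascular-disease–hypertension and depression–hypertension only in
the inactive stratum, so that default cohorts show more rule structure in
the IG, as the study population does. Boost sizes (log-OR 0.7–1.1) give
lifts in the 1.5–2.5 range actually seen in the reference tables.

Obesity is drawn as the 15th indicator and then *encoded* through height
and weight: BMI is sampled from a lognormal (meanlog log 23.8, sdlog 0.13)
truncated above or below 28 according to the indicator, and weight is
back-computed from BMI and a sex-dependent height. The cohort module
therefore re-derives obesity from anthropometrics exactly as it would on
real data. (Heights and weights are rounded to realistic precision, which
can flip a BMI within ~0.02 of the cut — about 0.1 % of participants —
and is far inside the Monte-Carlo bands the tests use.)

What the generator does **not** emulate: survey sampling weights,
household clustering, longitudinal panel structure, and any dependence of
disease risk on age, sex or education (demographics are drawn
independently of the conditions). Age is drawn per reported band and
uniformly within it, since only the band matters downstream. Passing tests
on synthetic cohorts therefore demonstrate the *pipeline's* correctness
under the assumed dependence structure, not that real comorbidity data
meet those assumptions.

## Numerical choices

* Threshold comparisons use exact integer counts
  (`100·count ≥ min_support·n`, `100·count_AB ≥ min_conf·count_A`,
  `count_AB·n > min_lift·count_A·count_B`) so rules at a threshold are
  classified without floating-point jitter; support/confidence thresholds
  are inclusive, the lift threshold strict, per the stated settings.
* Metrics are kept unrounded internally and rounded to 2 decimals only on
  output (`write_rules()`), matching the published table precision; the
  increase statistic is rounded to the nearest integer.
* Rules are emitted sorted by (consequent, antecedent), mirroring the
  reference tables' grouping and making runs byte-reproducible.
* Degenerate inputs: empty transaction sets and non-positive
  heights/weights are errors naming the offender; empty *transactions*
  (condition-free participants) are valid and only contribute to
  denominators; a cohort with all-zero marginals yields no conditions, no
  MCD and no rules.
* The brute-force oracle (`brute_force_rules()`) enumerates every itemset
  via bitmask superset-sums with no pruning and refuses vocabularies over
  18 items; it exists to check the Apriori path, not to be fast.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: hand
enumeration on toy transaction sets; equality of the Apriori and
brute-force paths on 100+ random instances (up to 15 items, 500
transactions); internal-consistency checks of the shipped reference
tables (support/confidence constant per antecedent within a stratum, as
it must be since the ratio is P(A)); recovery of planted
support/confidence/lift on an n = 20,000 synthetic cohort within 3
Monte-Carlo standard errors of the exact implied values; and a null
calibration showing that independence cohorts (n = 8,000, 20 seeds) emit
essentially no rules at the default thresholds — lift > 1.5 is far from
the null. These sizes keep the default suite under a minute while leaving
the statistical assertions well-powered.

## Known limitations

* The appearance-count discrepancy in the published comparison table
  (above) is documented, not resolved.
* Signature-diffing the two reference rule tables yields 15 IG-exclusive
  rules where the published text enumerates 14 (it omits
  {gonarthrosis, spondylosis} → diabetes, which is present in the IG table
  but absent from the AG table); both counts are surfaced.
* No statistical testing of rule-set differences and no multiple-testing
  control is performed — the comparison is descriptive, as in the source
  analysis.
* The miner is in-memory and level-wise; it is sized for tens of items
  and tens of thousands of transactions, not for retail-scale baskets.
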