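---
title: "Methods: evaluating simultaneous FINDRISC + HbA1c screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating simultaneous FINDRISC + HbA1c screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoscreen)
```

## The screening problem

A large share of diabetes is undiagnosed, and the diagnostic reference —
the 75-g oral glucose tolerance test (OGTT) — requires fasting and a 2-hour
clinic visit, which makes it unusable as a first-line screen. Two
non-fasting instruments are practical in opportunistic settings: the
Finnish Diabetes Risk Score (FINDRISC), an eight-item questionnaire, and
the HbA1c laboratory test. Each alone has a known weakness: HbA1c at its
diagnostic cutoff is very specific but insensitive, and a risk score alone
is noisy. This package implements the machinery to evaluate each
instrument, and their *simultaneous* (parallel, positive-on-either)
combination, against the OGTT reference on per-participant cohort data.

## Scoring and classification

`score_findrisc()` computes the eight sub-scores and total (0–26) from raw
fields. The point allocation is the original published FINDRISC table:
age <45/45–54/55–64/≥65 → 0/2/3/4; BMI <25/25–30/>30 → 0/1/3; waist
(male) <94/94–102/>102 → 0/3/4 and (female) <80/80–88/>88 → 0/3/4;
physical activity ≥30 min/day → 0 else 2; daily fruit/vegetables → 0 else
1; antihypertensive medication → 2; history of high glucose → 5; family
history none/second-degree/first-degree → 0/3/5. Two conventions are fixed
and test-pinned:

* **Band boundaries are closed on the lower-risk side** — age exactly 45
  scores 2, BMI exactly 25 scores 1, a male waist of exactly 94 cm scores 3.
* **Daily physical activity** is the sum of commute, recreation and work
  minutes, thresholded at 30 min/day; **fruit/vegetable intake** is a
  boolean taken as given (when derived from a 24-h recall, any nonzero
  consumption on the recall day counts as daily intake).
* **Family history granularity**: national surveys do not always separate
  relatives the way the instrument's 3- vs 5-point split assumes; we map
  `none`/`second_degree`/`first_degree` to 0/3/5 and document this as a
  mapping convention rather than a claim about any particular survey.

`classify_glycemic()` maps (FPG, 2-h PG) to five mutually exclusive
classes. The prose bands "100–125 mg/dL" and "140–199 mg/dL" are resolved
as the half-open intervals **[100, 126)** and **[140, 200)** so the five
classes exactly partition the positive quadrant against the diabetes
thresholds FPG ≥ 126 / 2-h PG ≥ 200; without this resolution the 125–126
and 199–200 slivers would belong to no class. A property test sweeps a
glucose grid to confirm the partition is total and single-valued.

`apply_exclusions()` applies the analysis cascade in a fixed order (age
< 20; fasting outside [9, 24) h; missing HbA1c; missing FPG; missing 2-h
PG; self-reported diabetes). A record failing several criteria is tallied
once, at its first failing step, which makes the per-step tally
deterministic and conservative: survivors + tally always sum to the input.

## Test evaluation

Positivity is `>=` the cutoff for both FINDRISC and HbA1c. Parallel
combination is logical OR (simultaneous testing), serial is AND
(sequential testing). For pre-diabetes outcomes — including the isolated
IFG and isolated IGT subtypes — diabetes-class participants are removed
*before* any counting, so "non-diseased" always means non-diabetic.

Confusion cells may be survey-weighted (`use_weights = TRUE` uses
`survey_weight`); with unit weights they are raw counts. From the cells we
report sensitivity, specificity, crude PPV/NPV, their sum, the fraction
testing positive, and the ROC-plane distance
`sqrt((1-se)^2 + (1-sp)^2)`. Crude predictive values reflect the sample
prevalence; `prevalence_adjusted_predictive_values()` re-expresses them at
an external prevalence (typically survey-weighted) via Bayes' rule, and
`population_positive_fraction()` gives the implied screening workload.
Internally everything is computed at full precision; rounding to 2
decimals happens only when `write_report()` emits CSV.

## ROC analysis

`empirical_roc()` places one operating point at every distinct observed
score (plus the (0,0) anchor at an infinite threshold). Two AUC routes are
implemented and tested against each other to 1e-12: trapezoidal
integration of the curve and the rank/pair-counting (Mann–Whitney) form
with ties counting one half; with weights, pairs are weighted by the
product of subject weights. `delong_compare()` implements DeLong's test
for two correlated AUCs via midrank placement values, reporting a 1-df
chi-square; the weighted variant of the DeLong variance is deliberately
out of scope (weighted AUC *point estimates* are supported). Degenerate
inputs are handled explicitly: identical score vectors give chi-square 0
and p = 1; zero variance with unequal AUCs is an error rather than a
silent division.

`optimal_cutoff_by_distance()` minimises the ROC distance over interior
operating points, breaking exact ties toward the **higher** threshold —
the operationally cheaper choice (fewer screen-positives).

## Survey weighting

`weighted_prevalence()` is the weighted share with Kish's effective sample
size `(Σw)² / Σw²`; unit weights reproduce crude proportions, and the
estimate is invariant to rescaling the weights.
`normalize_multicycle_weights()` divides weights by the number of pooled
survey cycles. Design-based variance estimation (strata/PSU linearization,
replicate weights) is out of scope: none of the quantities evaluated here
carry design-based confidence intervals.

## The synthetic cohort generator

`generate_cohort()` emulates a morning-fasted adult examination cohort
with a five-class glycemic mixture. Its defaults *are* the study
conditions the package targets:

* class prevalences 0.5375 / 0.2708 / 0.0437 / 0.0951 / 0.0529 for
  NGT / iIFG / iIGT / IFG+IGT / DM;
* class-conditional means (SD) — FPG: 91.43 (5.70), 106.15 (5.04),
  93.19 (5.23), 109.26 (6.67), 133.67 (42.64) mg/dL; 2-h PG: 93.35
  (21.80), 104.65 (21.38), 158.35 (14.89), 162.79 (15.74), 234.46 (76.40)
  mg/dL; HbA1c: 5.28 (0.35), 5.47 (0.38), 5.43 (0.38), 5.63 (0.38),
  6.24 (1.36) %; FINDRISC: 7.28 (4.39), 9.02 (4.56), 9.79 (4.31),
  11.32 (4.17), 11.66 (4.16).

Design choices, each made once:

* **Truncation = definition.** (FPG, 2-h PG) are drawn from truncated
  normals whose truncation region is exactly the assigned class's defining
  region, so reclassification consistency is 100% by construction. The
  diabetes class is a disjoint two-branch union — FPG-driven (FPG ≥ 126)
  vs 2-h-PG-driven (FPG < 126, 2-h PG ≥ 200) — with a configurable branch
  probability defaulting to 0.5, since the criteria are an "or".
* **Conditional independence given class.** The class-conditional
  marginals are all the descriptive table provides, so HbA1c, FINDRISC and
  the glucose pair are independent within a class by default; dependence
  enters through the class mixture, which is exactly what screening
  exploits. A Gaussian-copula `latent_correlation` knob can induce
  within-class HbA1c–FINDRISC correlation; it defaults to 0 and is
  documented as a simplification.
* **Discrete FINDRISC totals.** The total is a rounded truncated normal on
  the attainable totals (normal mass on [k−½, k+½], renormalized). Item
  sub-scores are then drawn uniformly among the 1728 item-category
  combinations that sum to the sampled total, and raw fields (age, BMI via
  height/weight, waist by sex, activity minutes, flags) are back-filled
  from interior draws of each category's band — so re-scoring the raw
  fields reproduces the sampled totals exactly, which is test-pinned.
* **Clean by default.** The defaults describe the *post-exclusion*
  analysis sample, so missingness and self-reported-diabetes rates are 0;
  the pre-exclusion population with its planted defect groups is built by
  `exclusion_fixture()`. Survey weights are log-normal(0, 0.5) and cycles
  uniform over 3 — plausible for pooled survey data; neither affects any
  unweighted quantity.

What the generator does **not** emulate: within-class correlations beyond
the optional copula knob; demographic realism beyond what FINDRISC items
need (sex is 50/50 and independent of class; race, income, smoking are
absent); measurement error or day-to-day glucose variability; any joint
behaviour of diet and activity. Consequently, passing recovery tests shows
the *pipeline* is correct against generator truth — it does not certify
performance numbers on real survey data, where the data-dependent
sensitivities, AUCs and chi-square statistics will differ.

## Numerical choices and degenerate inputs

* Truncated-normal draws use the inverse-CDF method; a truncation region
  with ~zero normal mass raises a configuration error.
* `metrics_from_confusion()` refuses empty disease or non-disease strata;
  PPV/NPV are `NA` (not an error) when no one tests positive/negative.
* The exclusion cascade is idempotent on its own output, and an empty
  cohort passes through with zero tallies.
* AUC equivalence (trapezoid vs rank) holds to 1e-12 under unit weights;
  ties are handled by midranks throughout.

## Problem sizes used by the test suite

Unit tests run on cohorts of a few hundred to a few thousand subjects;
the parameter-recovery test uses one 50,000-subject cohort with a fixed
seed, checking class prevalences, class-conditional HbA1c/FINDRISC means
and the operating points of `hba1c_test(6.5)` / `findrisc_test(9)` against
closed-form generator truth within 3 Monte-Carlo standard errors; the
AUC-equivalence property runs on 1,000 random small cohorts; the DeLong
variance is checked against a 2,000-replicate seeded bootstrap at n = 200.
These sizes were chosen so each check's Monte-Carlo error is small relative
to the tolerance it asserts.

## A small end-to-end run

```{r example}
cohort <- generate_cohort(2000, seed = 7)
report <- run_full_analysis(cohort, analysis_config(prevalence = 0.07))
report$sweep_diabetes[, c("cutoff", "sensitivity", "specificity",
                          "roc_distance")]
glance(report)
```

## Known limitations

* Weighted DeLong variance and design-based CIs are not provided.
* The pre-diabetes screening-yield column of a published cutoff table
  cannot be reproduced from a single prevalence by the workload formula;
  the package reports the formula-consistent value and both crude and
  prevalence-adjusted predictive values, leaving reconciliation of
  externally tabulated values to the analyst.
* HbA1c is always an index test here, never a reference standard.
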