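#' Weighted confusion counts for a binary test against a reference
#'
#' @param test Logical vector of index-test positivity.
#' @param disease Logical vector of reference-standard disease status.
#' @param weights Optional positive survey weights; `NULL` means unit weights,
#'   in which case the cells are the raw 2x2 counts.
#'
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`
#'   ((weighted) counts).
#' @export
build_confusion <- function(test, disease, weights = NULL) {
  if (length(test) != length(disease)) {
    abort("`test` and `disease` must have the same length.")
  }
  if (is.null(weights)) weights <- rep(1, length(test))
  if (length(weights) != length(test)) {
    abort("`weights` must match the length of `test`.")
  }
  if (any(is.na(test)) || any(is.na(disease)) || any(is.na(weights))) {
    abort("`test`, `disease` and `weights` must not contain missing values.")
  }
  if (any(weights <= 0)) abort("`weights` must be positive.")
  tibble(
    tp = sum(weights[test & disease]),
    fp = sum(weights[test & !disease]),
    tn = sum(weights[!test & !disease]),
    fn = sum(weights[!test & disease])
  )
}

#' Shortest distance to perfect classification on the ROC plane
#'
#' The Euclidean distance from an operating point to the top-left corner of
#' ROC space, `sqrt((1 - se)^2 + (1 - sp)^2)` with sensitivity and
#' specificity as proportions. Smaller is better; 0 is a perfect test and
#' the chance diagonal keeps it at or below sqrt(2).
#'
#' @param sensitivity,specificity Operating point in percent (0--100).
#'
#' @return Unitless distance in \[0, sqrt(2)\].
#' @examples
#' roc_distance(79.12, 51.40) # ~0.53
#' @export
roc_distance <- function(sensitivity, specificity) {
  for (x in list(sensitivity, specificity)) {
    if (any(!is.finite(x) | x < 0 | x > 100)) {
      abort("sensitivity and specificity must lie in [0, 100] percent.")
    }
  }
  sqrt((1 - sensitivity / 100)^2 + (1 - specificity / 100)^2)
}

#' Diagnostic accuracy metrics from confusion counts
#'
#' @param confusion A one-row tibble (or named list) with `tp`, `fp`, `tn`,
#'   `fn` as returned by [build_confusion()]; weighted counts are allowed.
#'
#' @return A one-row tibble with `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `sum` (sensitivity + specificity, percentage points), `roc_distance`,
#'   and `fraction_positive` (percent of the sample testing positive). All
#'   rate columns are percentages at full precision. `ppv` is `NA` when no
#'   one tests positive, `npv` when no one tests negative.
#' @export
metrics_from_confusion <- function(confusion) {
  cc <- as.list(confusion)
  tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  if (any(c(tp, fp, tn, fn) < 0)) abort("Confusion counts must be >= 0.")
  if (tp + fn <= 0) abort("No diseased subjects: sensitivity is undefined.")
  if (tn + fp <= 0) {
    abort("No non-diseased subjects: specificity is undefined.")
  }
  se <- 100 * tp / (tp + fn)
  sp <- 100 * tn / (tn + fp)
  total <- tp + fp + tn + fn
  tibble(
    sensitivity = se,
    specificity = sp,
    ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_,
    sum = se + sp,
    roc_distance = roc_distance(se, sp),
    fraction_positive = 100 * (tp + fp) / total
  )
}

#' Prevalence-adjusted predictive values
#'
#' Post-test probabilities at an externally supplied disease prevalence,
#' from Bayes' rule: `PPV = se * p / (se * p + (1 - sp)(1 - p))` and
#' `NPV = sp (1 - p) / ((1 - se) p + sp (1 - p))` with sensitivity and
#' specificity as proportions. This reconstructs predictive values on the
#' population scale (e.g. with a survey-weighted prevalence) rather than at
#' the crude sample prevalence.
#'
#' @param sensitivity,specificity Operating point in percent (0--100).
#' @param prevalence Disease prevalence as a proportion in (0, 1).
#'
#' @return A one-row tibble with `ppv` and `npv` in percent.
#' @examples
#' prevalence_adjusted_predictive_values(79.12, 51.40, 0.07)
#' @export
prevalence_adjusted_predictive_values <- function(sensitivity, specificity,
                                                  prevalence) {
  check_operating_point(sensitivity, specificity, prevalence)
  se <- sensitivity / 100
  sp <- specificity / 100
  p <- prevalence
  pos <- se * p + (1 - sp) * (1 - p)
  neg <- (1 - se) * p + sp * (1 - p)
  if (pos <= 0 || neg <= 0) {
    abort("Degenerate operating point: a predictive value is undefined.")
  }
  tibble(ppv = 100 * se * p / pos, npv = 100 * sp * (1 - p) / neg)
}

#' Expected fraction of the population screening positive
#'
#' `100 * (se * p + (1 - sp)(1 - p))`: the share of a population with disease
#' prevalence `p` that a test at the given operating point flags for
#' follow-up. This is the screening workload the strategy generates.
#'
#' @inheritParams prevalence_adjusted_predictive_values
#' @return Percent of the population testing positive.
#' @examples
#' population_positive_fraction(94.14, 20.90, 0.07) # ~80.2
#' @export
population_positive_fraction <- function(sensitivity, specificity,
                                         prevalence) {
  check_operating_point(sensitivity, specificity, prevalence)
  100 * (sensitivity / 100 * prevalence +
           (1 - specificity / 100) * (1 - prevalence))
}

check_operating_point <- function(sensitivity, specificity, prevalence) {
  for (x in list(sensitivity, specificity)) {
    if (any(!is.finite(x) | x < 0 | x > 100)) {
      abort("sensitivity and specificity must lie in [0, 100] percent.")
    }
  }
  if (any(!is.finite(prevalence) | prevalence <= 0 | prevalence >= 1)) {
    abort("`prevalence` must be a proportion strictly inside (0, 1).")
  }
  invisible(NULL)
}

disease_indicator <- function(class, target) {
  switch(target,
    diabetes = class == "DM",
    prediabetes = class %in% c("iIFG", "iIGT", "IFG_IGT"),
    iIFG = class == "iIFG",
    iIGT = class == "iIGT",
    abort(sprintf("Unknown target `%s`.", target))
  )
}

#' Evaluate a screening test against the OGTT reference
#'
#' Runs a [screening_test] on a classified, scored cohort and returns the
#' full diagnostic-accuracy row for the chosen outcome. For the pre-diabetes
#' outcome (and its isolated-IFG / isolated-IGT subtypes) participants with
#' undiagnosed diabetes are removed before any counting, so non-diseased
#' means "non-diabetic and without the target condition". An optional
#' minimum-age filter supports subgroup (e.g. >= 45 years) analyses.
#'
#' @param data Cohort tibble carrying `glycemic_class` (see
#'   [add_glycemic_class()]), `findrisc_total` and/or `hba1c` as the test
#'   requires, and `survey_weight` if `use_weights = TRUE`.
#' @param test A [screening_test].
#' @param target One of `"diabetes"`, `"prediabetes"`, `"iIFG"`, `"iIGT"`.
#' @param use_weights Use `survey_weight` for the confusion cells
#'   (default `FALSE`, i.e. raw counts).
#' @param min_age Optional minimum age in years; rows below it are dropped
#'   before evaluation.
#' @param prevalence Optional external prevalence (proportion) at which to
#'   additionally report prevalence-adjusted predictive values and the
#'   population screening-positive fraction (`ppv_adj`, `npv_adj`,
#'   `pct_population`).
#'
#' @return A one-row tibble: `test`, `target`, `n` (subjects evaluated),
#'   `n_disease`, then the [metrics_from_confusion()] columns, plus the three
#'   adjusted columns when `prevalence` is given.
#' @export
evaluate_model <- function(data, test, target = c("diabetes", "prediabetes",
                                                  "iIFG", "iIGT"),
                           use_weights = FALSE, min_age = NULL,
                           prevalence = NULL) {
  target <- match.arg(target)
  data <- as_tibble(data)
  if (!"glycemic_class" %in% names(data)) {
    abort("`data` must carry `glycemic_class`; run `add_glycemic_class()`.")
  }
  if (!is.null(min_age)) data <- filter(data, .data$age >= min_age)
  if (target != "diabetes") data <- filter(data, .data$glycemic_class != "DM")
  if (nrow(data) == 0L) abort("No subjects left after filtering.")
  disease <- disease_indicator(data$glycemic_class, target)
  weights <- if (use_weights) data$survey_weight else NULL
  confusion <- build_confusion(apply_test(test, data), disease, weights)
  out <- bind_cols(
    tibble(test = format(test), target = target,
           n = nrow(data), n_disease = sum(disease)),
    metrics_from_confusion(confusion)
  )
  if (!is.null(prevalence)) {
    pv <- prevalence_adjusted_predictive_values(
      out$sensitivity, out$specificity, prevalence)
    out$ppv_adj <- pv$ppv
    out$npv_adj <- pv$npv
    out$pct_population <- population_positive_fraction(
      out$sensitivity, out$specificity, prevalence)
  }
  out
}

#' Sweep FINDRISC cutoffs and tabulate accuracy per cutoff
#'
#' Evaluates `findrisc_test(cutoff)` for each cutoff and binds the resulting
#' metric rows, yielding the familiar cutoff-sweep table (sensitivity,
#' specificity, predictive values, sum, ROC distance, fraction positive) for
#' one outcome.
#'
#' @inheritParams evaluate_model
#' @param cutoffs Integer vector of FINDRISC cutoffs to evaluate
#'   (default 5:9).
#'
#' @return A tibble with one row per cutoff, led by a `cutoff` column.
#' @export
sweep_findrisc_cutoffs <- function(data, cutoffs = 5:9,
                                   target = c("diabetes", "prediabetes",
                                              "iIFG", "iIGT"),
                                   use_weights = FALSE, min_age = NULL,
                                   prevalence = NULL) {
  target <- match.arg(target)
  if (length(cutoffs) == 0) abort("`cutoffs` must be non-empty.")
  purrr::map_dfr(cutoffs, function(k) {
    row <- evaluate_model(data, findrisc_test(k), target,
                          use_weights = use_weights, min_age = min_age,
                          prevalence = prevalence)
    bind_cols(tibble(cutoff = k), row)
  })
}
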