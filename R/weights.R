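#' Survey-weighted prevalence of a condition
#'
#' Estimates the population prevalence of a condition as the weighted share
#' of participants satisfying it, `sum(w * 1[cond]) / sum(w)`, together with
#' Kish's effective sample size `(sum w)^2 / sum(w^2)`. With unit weights the
#' estimate reduces to the crude sample proportion and the effective n to the
#' raw n.
#'
#' @param data Cohort data frame.
#' @param condition Unquoted logical expression evaluated within `data`
#'   (e.g. `glycemic_class == "DM"`).
#' @param weights Unquoted column of positive survey weights; defaults to
#'   `survey_weight`. Use `NULL` for unit weights.
#'
#' @return A one-row tibble with `estimate` (proportion), `effective_n`, and
#'   the raw `n`.
#' @export
weighted_prevalence <- function(data, condition, weights = survey_weight) {
  data <- as_tibble(data)
  if (nrow(data) == 0L) abort("Prevalence undefined on an empty cohort.")
  cond <- eval_tidy(enquo(condition), data)
  if (!is.logical(cond) || anyNA(cond)) {
    abort("`condition` must evaluate to a logical vector without NAs.")
  }
  wq <- enquo(weights)
  w <- if (quo_is_null(wq)) rep(1, nrow(data)) else eval_tidy(wq, data)
  if (any(is.na(w)) || any(w <= 0)) abort("Weights must be positive.")
  tibble(
    estimate = sum(w * cond) / sum(w),
    effective_n = sum(w)^2 / sum(w^2),
    n = nrow(data)
  )
}

#' Rescale survey weights when pooling multiple survey cycles
#'
#' When several independent survey cycles are concatenated, each record's
#' weight is divided by the number of cycles pooled so that the combined
#' weights still sum to one population total rather than several. Relative
#' weights within a cycle are preserved.
#'
#' @param data Cohort data frame with a `survey_weight` column.
#' @param n_cycles Number of pooled cycles (positive integer).
#'
#' @return The tibble with `survey_weight` divided by `n_cycles`.
#' @export
normalize_multicycle_weights <- function(data, n_cycles) {
  if (!is.numeric(n_cycles) || length(n_cycles) != 1 || n_cycles < 1 ||
      n_cycles != round(n_cycles)) {
    abort("`n_cycles` must be a positive integer.")
  }
  data <- as_tibble(data)
  if (!"survey_weight" %in% names(data)) {
    abort("`data` must carry a `survey_weight` column.")
  }
  mutate(data, survey_weight = .data$survey_weight / n_cycles)
}
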