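#' Classify glycemic status from fasting and 2-h post-load glucose
#'
#' Assigns each (FPG, 2-h PG) pair to one of five mutually exclusive classes
#' following the ADA plasma-glucose criteria: undiagnosed diabetes (`DM`) when
#' FPG >= 126 mg/dL or 2-h PG >= 200 mg/dL; otherwise combined impaired
#' fasting glucose and impaired glucose tolerance (`IFG_IGT`) when FPG is in
#' \[100, 126) and 2-h PG in \[140, 200); isolated IFG (`iIFG`) when only the
#' fasting band is met; isolated IGT (`iIGT`) when only the post-load band is
#' met; and normal glucose tolerance (`NGT`) otherwise. The pre-diabetes
#' glucose bands are taken as half-open intervals \[100, 126) and \[140, 200)
#' so that the five classes partition the whole positive quadrant.
#'
#' @param fpg Fasting plasma glucose in mg/dL (> 0, no missing values).
#' @param pg2h 2-hour post-load plasma glucose in mg/dL (> 0, no missing
#'   values).
#'
#' @return A factor with levels `NGT`, `iIFG`, `iIGT`, `IFG_IGT`, `DM`.
#' @examples
#' classify_glycemic(c(95, 105, 105, 95, 126), c(120, 120, 150, 150, 100))
#' @export
classify_glycemic <- function(fpg, pg2h) {
  if (length(fpg) != length(pg2h)) {
    abort("`fpg` and `pg2h` must have the same length.")
  }
  if (any(is.na(fpg)) || any(is.na(pg2h))) {
    abort("`fpg` and `pg2h` must not contain missing values.")
  }
  if (any(fpg <= 0) || any(pg2h <= 0)) {
    abort("`fpg` and `pg2h` must be positive (mg/dL).")
  }
  cls <- dplyr::case_when(
    fpg >= 126 | pg2h >= 200 ~ "DM",
    fpg >= 100 & pg2h >= 140 ~ "IFG_IGT",
    fpg >= 100 ~ "iIFG",
    pg2h >= 140 ~ "iIGT",
    TRUE ~ "NGT"
  )
  factor(cls, levels = GLYCEMIC_LEVELS)
}

#' Add the glycemic class column to a cohort table
#'
#' @param data A data frame with positive, non-missing `fpg` and `pg2h`
#'   columns (mg/dL).
#' @return The input tibble with a `glycemic_class` factor column appended.
#' @export
add_glycemic_class <- function(data) {
  data <- as_tibble(data)
  data$glycemic_class <- classify_glycemic(data$fpg, data$pg2h)
  data
}

exclusion_steps <- function() {
  c("age_lt_20", "fasting_out_of_range", "missing_hba1c",
    "missing_fpg", "missing_pg2h", "self_reported_diabetes")
}

#' Apply the study exclusion cascade
#'
#' Sequentially removes participants who are (1) younger than 20 years,
#' (2) fasted less than 9 or at least 24 hours, (3) missing HbA1c,
#' (4) missing FPG, (5) missing the 2-h OGTT glucose, or (6) report a prior
#' diabetes diagnosis. A record failing several criteria is excluded once and
#' tallied at the first failing step, so the per-step counts are deterministic
#' and sum (with the survivors) to the input size.
#'
#' @param data Cohort tibble with columns `age`, `fasting_hours`, `hba1c`,
#'   `fpg`, `pg2h` (missing values as `NA`) and `self_reported_diabetes`.
#'
#' @return The retained tibble, with the named per-step tally attached as
#'   attribute `"exclusion_tally"` (retrieve it with [exclusion_tally()]).
#' @export
apply_exclusions <- function(data) {
  data <- as_tibble(data)
  needed <- c("age", "fasting_hours", "hba1c", "fpg", "pg2h",
              "self_reported_diabetes")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Column(s) required for exclusions missing: %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  fails <- cbind(
    age_lt_20 = !is.na(data$age) & data$age < 20,
    fasting_out_of_range = !is.na(data$fasting_hours) &
      (data$fasting_hours < 9 | data$fasting_hours >= 24),
    missing_hba1c = is.na(data$hba1c),
    missing_fpg = is.na(data$fpg),
    missing_pg2h = is.na(data$pg2h),
    self_reported_diabetes = !is.na(data$self_reported_diabetes) &
      data$self_reported_diabetes
  )
  # first failing step per row (0 = retained)
  first_fail <- apply(fails, 1L, function(z) {
    w <- which(z)
    if (length(w) == 0L) 0L else w[[1L]]
  })
  if (nrow(data) == 0L) first_fail <- integer(0)
  tally <- vapply(seq_along(exclusion_steps()),
                  function(k) sum(first_fail == k), integer(1))
  names(tally) <- exclusion_steps()
  retained <- data[first_fail == 0L, , drop = FALSE]
  attr(retained, "exclusion_tally") <- tally
  retained
}

#' Retrieve the exclusion tally from a filtered cohort
#'
#' @param data A tibble returned by [apply_exclusions()].
#' @param as_json If `TRUE`, return the tally as a JSON object string
#'   `{"step": count, ...}` instead of a named integer vector.
#' @return Named integer vector of per-step exclusion counts, or a JSON
#'   string.
#' @export
exclusion_tally <- function(data, as_json = FALSE) {
  tally <- attr(data, "exclusion_tally")
  if (is.null(tally)) {
    abort("`data` carries no exclusion tally; run `apply_exclusions()` first.")
  }
  if (as_json) {
    return(jsonlite::toJSON(as.list(tally), auto_unbox = TRUE))
  }
  tally
}
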