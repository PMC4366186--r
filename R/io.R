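cohort_col_types <- function() {
  readr::cols(
    id = readr::col_character(),
    age = readr::col_double(),
    sex = readr::col_character(),
    height = readr::col_double(),
    weight = readr::col_double(),
    waist = readr::col_double(),
    uses_antihypertensive_med = readr::col_logical(),
    history_high_glucose = readr::col_logical(),
    family_history = readr::col_character(),
    pa_minutes_commute = readr::col_double(),
    pa_minutes_recreation = readr::col_double(),
    pa_minutes_work = readr::col_double(),
    fruit_veg_daily = readr::col_logical(),
    fpg = readr::col_double(),
    pg2h = readr::col_double(),
    hba1c = readr::col_double(),
    fasting_hours = readr::col_double(),
    self_reported_diabetes = readr::col_logical(),
    survey_weight = readr::col_double(),
    survey_cycle = readr::col_integer()
  )
}

validate_cohort <- function(data) {
  checks <- list(
    list("age", function(x) is.na(x) | x >= 0, "age must be >= 0"),
    list("height", function(x) is.na(x) | x > 0, "height must be > 0"),
    list("weight", function(x) is.na(x) | x > 0, "weight must be > 0"),
    list("waist", function(x) is.na(x) | x > 0, "waist must be > 0"),
    list("fpg", function(x) is.na(x) | x > 0, "fpg must be > 0"),
    list("pg2h", function(x) is.na(x) | x > 0, "pg2h must be > 0"),
    list("hba1c", function(x) is.na(x) | x > 0, "hba1c must be > 0"),
    list("fasting_hours", function(x) is.na(x) | x >= 0,
         "fasting_hours must be >= 0"),
    list("survey_weight", function(x) !is.na(x) & x > 0,
         "survey_weight must be > 0")
  )
  problems <- character(0)
  for (ck in checks) {
    col <- ck[[1]]
    if (!col %in% names(data)) next
    bad <- which(!ck[[2]](data[[col]]))
    if (length(bad) > 0) {
      problems <- c(problems, sprintf(
        "%s (rows %s)", ck[[3]], paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid cohort values:\n  ",
                 paste(problems, collapse = "\n  ")))
  }
  invisible(data)
}

#' Read and write cohort CSV files
#'
#' The cohort CSV carries one row per participant with header names matching
#' the participant-record fields (see [generate_cohort()] for the schema);
#' missing laboratory values are empty cells. Reading validates numeric
#' ranges and reports row-indexed errors; a write-then-read round trip
#' preserves values and missingness.
#'
#' @param path File path.
#' @param data Cohort tibble.
#'
#' @return `read_cohort()` returns a validated tibble; `write_cohort()`
#'   invisibly returns `path`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (file.size(path) == 0) abort(sprintf("Empty cohort file: %s", path))
  spec <- cohort_col_types()
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  required <- setdiff(names(spec$cols), c("id", "survey_cycle"))
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0) {
    abort(sprintf("Cohort file is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  spec$cols <- spec$cols[intersect(names(spec$cols), header)]
  data <- readr::read_csv(path, col_types = spec, show_col_types = FALSE)
  parse_problems <- readr::problems(data)
  if (nrow(parse_problems) > 0) {
    abort(sprintf(
      "Malformed cohort CSV: %d parse problem(s); first at row %d (%s).",
      nrow(parse_problems), parse_problems$row[1], parse_problems$expected[1]))
  }
  validate_cohort(data)
  data
}

#' @rdname read_cohort
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(as_tibble(data), path, na = "")
  invisible(path)
}

round_numeric <- function(df, digits = 2) {
  mutate(df, across(dplyr::where(is.numeric), ~ round(.x, digits)))
}

#' Write a screening report to disk
#'
#' Writes the tabular blocks of a [run_full_analysis()] report as CSV files
#' (percentages rounded to 2 decimals, mirroring the usual presentation
#' precision) plus a single `report.json` holding every block at full
#' precision, including exclusion tallies, AUCs and DeLong comparisons.
#'
#' @param report A `screening_report`.
#' @param dir Output directory (created if needed).
#'
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "screening_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  blocks <- list(
    descriptives = report$descriptives,
    sweep_diabetes = report$sweep_diabetes,
    sweep_prediabetes = report$sweep_prediabetes,
    models = report$models
  )
  if (!is.null(report$models_min_age)) {
    blocks$models_min_age <- report$models_min_age
  }
  paths <- character(0)
  for (nm in names(blocks)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(round_numeric(blocks[[nm]]), p)
    paths <- c(paths, p)
  }
  json <- list(
    n = report$n,
    exclusions = as.list(report$exclusions),
    prevalence = report$prevalence,
    descriptives = report$descriptives,
    sweep_diabetes = report$sweep_diabetes,
    sweep_prediabetes = report$sweep_prediabetes,
    models = report$models,
    auc = purrr::map(report$roc, auc_trapezoidal),
    delong = purrr::map(report$delong, ~ as.list(unclass(.x)))
  )
  if (!is.null(report$models_min_age)) {
    json$models_min_age <- report$models_min_age
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(json, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, jp))
}
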