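#' Body mass index from weight and height
#'
#' @param weight Body weight in kilograms (> 0).
#' @param height Standing height in centimetres (> 0).
#'
#' @return Numeric vector of BMI values in kg/m^2.
#' @examples
#' compute_bmi(100, 200) # 25
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.finite(weight) | weight <= 0)) {
    abort("`weight` must be a positive finite number of kilograms.")
  }
  if (any(!is.finite(height) | height <= 0)) {
    abort("`height` must be a positive finite number of centimetres.")
  }
  weight / (height / 100)^2
}

#' Total daily physical-activity minutes
#'
#' Sums minutes of physical activity across the three domains recorded in the
#' cohort: commuting, recreation, and work.
#'
#' @param commute,recreation,work Minutes per day in each domain (>= 0).
#'
#' @return Numeric vector of total minutes per day.
#' @export
derive_pa_minutes <- function(commute, recreation, work) {
  for (nm in c("commute", "recreation", "work")) {
    x <- get(nm)
    if (any(!is.finite(x) | x < 0)) {
      abort(sprintf("`%s` minutes must be non-negative and finite.", nm))
    }
  }
  commute + recreation + work
}

# Item scorers for the original published FINDRISC point allocation.
# Bands are closed on the lower-risk side: the stated boundary value earns
# the higher-risk points (age 45 -> 2, BMI 25 -> 1, male waist 94 -> 3, ...).
findrisc_age_points <- function(age) {
  dplyr::case_when(age < 45 ~ 0L, age < 55 ~ 2L, age < 65 ~ 3L, TRUE ~ 4L)
}

findrisc_bmi_points <- function(bmi) {
  dplyr::case_when(bmi < 25 ~ 0L, bmi <= 30 ~ 1L, TRUE ~ 3L)
}

findrisc_waist_points <- function(waist, sex) {
  lo <- ifelse(sex == "male", 94, 80)
  hi <- ifelse(sex == "male", 102, 88)
  dplyr::case_when(waist < lo ~ 0L, waist <= hi ~ 3L, TRUE ~ 4L)
}

findrisc_pa_points <- function(pa_minutes) {
  ifelse(pa_minutes >= 30, 0L, 2L)
}

findrisc_fruitveg_points <- function(fruit_veg_daily) {
  ifelse(fruit_veg_daily, 0L, 1L)
}

findrisc_med_points <- function(uses_antihypertensive_med) {
  ifelse(uses_antihypertensive_med, 2L, 0L)
}

findrisc_glucose_points <- function(history_high_glucose) {
  ifelse(history_high_glucose, 5L, 0L)
}

findrisc_family_points <- function(family_history) {
  dplyr::case_when(
    family_history == "none" ~ 0L,
    family_history == "second_degree" ~ 3L,
    family_history == "first_degree" ~ 5L
  )
}

# Attainable point sets per item, in a fixed column order.
findrisc_point_sets <- function() {
  list(
    age_pts       = c(0L, 2L, 3L, 4L),
    bmi_pts       = c(0L, 1L, 3L),
    waist_pts     = c(0L, 3L, 4L),
    pa_pts        = c(0L, 2L),
    fruitveg_pts  = c(0L, 1L),
    med_pts       = c(0L, 2L),
    glucose_hist_pts = c(0L, 5L),
    family_pts    = c(0L, 3L, 5L)
  )
}

#' Enumerate all FINDRISC item-score combinations
#'
#' Expands the full cross-product of attainable sub-scores for the eight
#' FINDRISC items (4 x 3 x 3 x 2 x 2 x 2 x 2 x 3 = 1728 combinations) together
#' with the implied total. Used for brute-force checks of the score range and
#' for back-filling item scores in the synthetic cohort generator.
#'
#' @return A tibble with one row per combination: the eight `*_pts` columns
#'   and `findrisc_total`.
#' @export
enumerate_findrisc_profiles <- function() {
  grid <- expand.grid(findrisc_point_sets(), KEEP.OUT.ATTRS = FALSE)
  grid$findrisc_total <- as.integer(rowSums(grid))
  as_tibble(grid)
}

findrisc_required_items <- function() {
  list(
    age = "age", sex = "sex", height = "height", weight = "weight",
    waist = "waist",
    uses_antihypertensive_med = "uses_antihypertensive_med",
    history_high_glucose = "history_high_glucose",
    family_history = "family_history",
    pa_minutes_commute = "pa_minutes_commute",
    pa_minutes_recreation = "pa_minutes_recreation",
    pa_minutes_work = "pa_minutes_work",
    fruit_veg_daily = "fruit_veg_daily"
  )
}

#' Score the Finnish Diabetes Risk Score (FINDRISC)
#'
#' Computes the eight FINDRISC item sub-scores and their total (0--26) for
#' every row of a participant table. The instrument's items are age, BMI,
#' waist circumference, daily physical activity (>= 30 min/day summed over
#' commuting, recreation and work), daily fruit/vegetable consumption,
#' antihypertensive medication use, history of high blood glucose, and family
#' history of diabetes.
#'
#' Category boundaries are closed on the lower-risk side: age exactly 45
#' scores 2, BMI exactly 25 scores 1, a male waist of exactly 94 cm scores 3,
#' and so on for every band.
#'
#' @param data A data frame with one row per participant carrying the columns
#'   `age`, `sex` (`"male"`/`"female"`), `height` (cm), `weight` (kg), `waist`
#'   (cm), `uses_antihypertensive_med` (logical), `history_high_glucose`
#'   (logical), `family_history` (`"none"`, `"second_degree"`,
#'   `"first_degree"`), `pa_minutes_commute`, `pa_minutes_recreation`,
#'   `pa_minutes_work` (minutes/day), and `fruit_veg_daily` (logical).
#'
#' @return The input tibble with nine added columns: `age_pts`, `bmi_pts`,
#'   `waist_pts`, `pa_pts`, `fruitveg_pts`, `med_pts`, `glucose_hist_pts`,
#'   `family_pts`, and `findrisc_total`.
#' @examples
#' tibble::tibble(
#'   age = 50, sex = "male", height = 175, weight = 83, waist = 96,
#'   uses_antihypertensive_med = TRUE, history_high_glucose = FALSE,
#'   family_history = "second_degree", pa_minutes_commute = 0,
#'   pa_minutes_recreation = 10, pa_minutes_work = 5, fruit_veg_daily = TRUE
#' ) |> score_findrisc()
#' @export
score_findrisc <- function(data) {
  data <- as_tibble(data)
  items <- findrisc_required_items()
  missing_cols <- setdiff(names(items), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "FINDRISC item column(s) missing from `data`: %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in names(items)) {
    bad <- which(is.na(data[[col]]))
    if (length(bad) > 0) {
      abort(sprintf(
        "FINDRISC item `%s` is missing for row(s) %s.",
        col, paste(utils::head(bad, 5), collapse = ", ")
      ))
    }
  }
  if (!all(data$sex %in% c("male", "female"))) {
    abort("`sex` must be \"male\" or \"female\".")
  }
  if (!all(data$family_history %in% c("none", "second_degree", "first_degree"))) {
    abort("`family_history` must be none, second_degree or first_degree.")
  }

  bmi <- compute_bmi(data$weight, data$height)
  pa <- derive_pa_minutes(
    data$pa_minutes_commute, data$pa_minutes_recreation, data$pa_minutes_work
  )
  scored <- data %>%
    mutate(
      age_pts = findrisc_age_points(.data$age),
      bmi_pts = findrisc_bmi_points(bmi),
      waist_pts = findrisc_waist_points(.data$waist, .data$sex),
      pa_pts = findrisc_pa_points(pa),
      fruitveg_pts = findrisc_fruitveg_points(.data$fruit_veg_daily),
      med_pts = findrisc_med_points(.data$uses_antihypertensive_med),
      glucose_hist_pts = findrisc_glucose_points(.data$history_high_glucose),
      family_pts = findrisc_family_points(.data$family_history)
    )
  scored$findrisc_total <- as.integer(
    scored$age_pts + scored$bmi_pts + scored$waist_pts + scored$pa_pts +
      scored$fruitveg_pts + scored$med_pts + scored$glucose_hist_pts +
      scored$family_pts
  )
  stopifnot(all(scored$findrisc_total >= 0L & scored$findrisc_total <= 26L))
  scored
}
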