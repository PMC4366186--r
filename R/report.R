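#' Analysis configuration for the screening pipeline
#'
#' @param findrisc_cutoffs Cutoffs for the FINDRISC sweep (default 5:9).
#' @param findrisc_cutoff The single FINDRISC cutoff used in the model
#'   comparison (default 9, the shortest-distance optimum in the source
#'   population).
#' @param hba1c_cutoff_diabetes,hba1c_cutoff_prediabetes HbA1c positivity
#'   cutoffs in percent (defaults 6.5 and 5.7, the ADA diagnostic and
#'   pre-diabetes thresholds).
#' @param use_weights Survey-weight the confusion counts (default `FALSE`).
#' @param min_age Optional minimum age (e.g. 45) for a subgroup analysis;
#'   `NULL` analyses all adults.
#' @param prevalence Optional external prevalence (proportion) for
#'   prevalence-adjusted predictive values in the sweeps.
#'
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(findrisc_cutoffs = 5:9,
                            findrisc_cutoff = 9,
                            hba1c_cutoff_diabetes = 6.5,
                            hba1c_cutoff_prediabetes = 5.7,
                            use_weights = FALSE,
                            min_age = NULL,
                            prevalence = NULL) {
  if (length(findrisc_cutoffs) == 0) abort("Cutoff sweep must be non-empty.")
  if (any(findrisc_cutoffs < 0 | findrisc_cutoffs > 26)) {
    abort("FINDRISC cutoffs must lie in 0..26.")
  }
  if (hba1c_cutoff_diabetes <= 0 || hba1c_cutoff_prediabetes <= 0) {
    abort("HbA1c cutoffs must be positive percentages.")
  }
  structure(
    list(findrisc_cutoffs = findrisc_cutoffs,
         findrisc_cutoff = findrisc_cutoff,
         hba1c_cutoff_diabetes = hba1c_cutoff_diabetes,
         hba1c_cutoff_prediabetes = hba1c_cutoff_prediabetes,
         use_weights = use_weights, min_age = min_age,
         prevalence = prevalence),
    class = "analysis_config"
  )
}

descriptive_summary <- function(data) {
  data %>%
    group_by(.data$glycemic_class) %>%
    summarise(
      n = dplyr::n(),
      pct = 100 * dplyr::n() / nrow(data),
      weighted_pct = 100 * sum(.data$survey_weight) /
        sum(data$survey_weight),
      across(c("age", "fpg", "pg2h", "hba1c", "findrisc_total"),
             list(mean = mean, sd = sd)),
      .groups = "drop"
    )
}

model_comparison_rows <- function(data, config, min_age = NULL) {
  purrr::map_dfr(
    c("diabetes", "prediabetes", "iIFG", "iIGT"),
    function(target) {
      a1c_cut <- if (target == "diabetes") config$hba1c_cutoff_diabetes
      else config$hba1c_cutoff_prediabetes
      tests <- list(
        hba1c_alone = hba1c_test(a1c_cut),
        findrisc_alone = findrisc_test(config$findrisc_cutoff),
        simultaneous = parallel_or(findrisc_test(config$findrisc_cutoff),
                                   hba1c_test(a1c_cut))
      )
      purrr::imap_dfr(tests, function(tst, label) {
        bind_cols(
          tibble(model = label),
          evaluate_model(data, tst, target,
                         use_weights = config$use_weights,
                         min_age = min_age,
                         prevalence = config$prevalence)
        )
      })
    }
  )
}

#' Run the full opportunistic-screening analysis
#'
#' Executes the whole pipeline on a cohort: FINDRISC scoring (if raw fields
#' are present and `findrisc_total` is not), glycemic classification, the
#' exclusion cascade, a descriptive class summary, FINDRISC cutoff sweeps for
#' diabetes and pre-diabetes (diabetes excluded for the latter), the
#' three-model comparison (HbA1c alone, FINDRISC alone, simultaneous
#' OR-combination) for diabetes, pre-diabetes and the isolated IFG/IGT
#' subtypes, ROC curves with AUCs and a DeLong comparison of FINDRISC vs
#' HbA1c, weighted prevalences, and optionally the same model comparison
#' restricted to participants aged `min_age` and above.
#'
#' @param cohort Cohort tibble (e.g. from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config An [analysis_config()].
#'
#' @return A list of class `screening_report` with elements `descriptives`,
#'   `sweep_diabetes`, `sweep_prediabetes`, `models`, `roc`, `prevalence`,
#'   `exclusions`, and (when `min_age` is set) `models_min_age`.
#' @export
run_full_analysis <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- as_tibble(cohort)
  cohort <- apply_exclusions(cohort)
  tally <- exclusion_tally(cohort)
  if (!"findrisc_total" %in% names(cohort)) {
    cohort <- score_findrisc(cohort)
  }
  cohort <- add_glycemic_class(cohort)

  prev <- purrr::map_dfr(
    c(diabetes = "DM", prediabetes = "prediabetes"),
    function(tgt) {
      cond <- if (tgt == "DM") cohort$glycemic_class == "DM"
      else cohort$glycemic_class %in% c("iIFG", "iIGT", "IFG_IGT")
      cohort %>%
        mutate(.cond = cond) %>%
        weighted_prevalence(.data$.cond)
    },
    .id = "outcome"
  )

  non_dm <- filter(cohort, .data$glycemic_class != "DM")
  roc_list <- list(
    findrisc_diabetes = empirical_roc(cohort, .data$findrisc_total,
                                      .data$glycemic_class == "DM"),
    hba1c_diabetes = empirical_roc(cohort, .data$hba1c,
                                   .data$glycemic_class == "DM"),
    findrisc_prediabetes = empirical_roc(
      non_dm, .data$findrisc_total,
      .data$glycemic_class %in% c("iIFG", "iIGT", "IFG_IGT")),
    hba1c_prediabetes = empirical_roc(
      non_dm, .data$hba1c,
      .data$glycemic_class %in% c("iIFG", "iIGT", "IFG_IGT"))
  )
  delong <- list(
    diabetes = delong_compare(cohort, .data$findrisc_total, .data$hba1c,
                              .data$glycemic_class == "DM"),
    prediabetes = delong_compare(
      non_dm, .data$findrisc_total, .data$hba1c,
      .data$glycemic_class %in% c("iIFG", "iIGT", "IFG_IGT"))
  )

  report <- list(
    n = nrow(cohort),
    exclusions = tally,
    descriptives = descriptive_summary(cohort),
    sweep_diabetes = sweep_findrisc_cutoffs(
      cohort, config$findrisc_cutoffs, "diabetes",
      use_weights = config$use_weights, prevalence = config$prevalence),
    sweep_prediabetes = sweep_findrisc_cutoffs(
      cohort, config$findrisc_cutoffs, "prediabetes",
      use_weights = config$use_weights, prevalence = config$prevalence),
    models = model_comparison_rows(cohort, config),
    roc = roc_list,
    delong = delong,
    prevalence = prev,
    config = config
  )
  if (!is.null(config$min_age)) {
    report$models_min_age <- model_comparison_rows(
      cohort, config, min_age = config$min_age)
  }
  structure(report, class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> n = %d after exclusions\n", x$n))
  cat("Prevalence (weighted):\n")
  print(as.data.frame(x$prevalence), row.names = FALSE)
  cat("\nModel comparison (first rows):\n")
  print(utils::head(as.data.frame(
    x$models[, c("model", "target", "sensitivity", "specificity")]), 6),
    row.names = FALSE)
  invisible(x)
}

#' @rdname run_full_analysis
#' @param x,object A `screening_report`.
#' @param ... Unused.
#' @export
tidy.screening_report <- function(x, ...) {
  x$models
}

#' @rdname run_full_analysis
#' @export
glance.screening_report <- function(x, ...) {
  tibble(
    n = x$n,
    prevalence_diabetes = x$prevalence$estimate[
      x$prevalence$outcome == "diabetes"],
    prevalence_prediabetes = x$prevalence$estimate[
      x$prevalence$outcome == "prediabetes"],
    auc_findrisc_diabetes = auc_trapezoidal(x$roc$findrisc_diabetes),
    auc_hba1c_diabetes = auc_trapezoidal(x$roc$hba1c_diabetes),
    auc_findrisc_prediabetes = auc_trapezoidal(x$roc$findrisc_prediabetes),
    auc_hba1c_prediabetes = auc_trapezoidal(x$roc$hba1c_prediabetes),
    delong_chi_square_diabetes = x$delong$diabetes$chi_square,
    delong_p_diabetes = x$delong$diabetes$p_value
  )
}

#' Plot the three-model sensitivity/specificity comparison
#'
#' Bar chart of sensitivity and specificity for HbA1c alone, FINDRISC alone
#' and the simultaneous OR-combination, by outcome.
#'
#' @param report A `screening_report`.
#' @return A ggplot object.
#' @export
plot_model_comparison <- function(report) {
  stopifnot(inherits(report, "screening_report"))
  df <- report$models %>%
    select("model", "target", "sensitivity", "specificity") %>%
    tidyr::pivot_longer(c("sensitivity", "specificity"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~target) +
    ggplot2::labs(x = NULL, y = "Percent", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
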