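# Inverse-CDF sampler for a normal truncated to [lo, hi].
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  if (any(p_hi - p_lo < 1e-12)) {
    abort(sprintf(
      "Infeasible truncation: N(%g, %g) has ~zero mass on [%g, %g].",
      mean[1], sd[1], lo[1], hi[1]))
  }
  qnorm(p_lo + runif(n) * (p_hi - p_lo), mean, sd)
}

#' Discretized truncated-normal distribution of the FINDRISC total
#'
#' Probability mass function over the attainable FINDRISC totals obtained by
#' rounding a normal to the nearest integer and truncating to the score's
#' 0--26 range: the mass at `k` is the normal probability of
#' `[k - 1/2, k + 1/2]`, renormalized over the attainable totals.
#'
#' @param mean,sd Mean and standard deviation of the underlying normal
#'   (score units).
#' @return A tibble with columns `total` (0--26) and `prob` (sums to 1).
#' @export
findrisc_total_pmf <- function(mean, sd) {
  if (sd <= 0) abort("`sd` must be positive.")
  totals <- sort(unique(enumerate_findrisc_profiles()$findrisc_total))
  p <- pnorm(totals + 0.5, mean, sd) - pnorm(totals - 0.5, mean, sd)
  if (sum(p) <= 0) abort("Degenerate FINDRISC total distribution.")
  tibble(total = totals, prob = p / sum(p))
}

#' Default synthetic-cohort configuration
#'
#' Parameter set for [generate_cohort()] describing an NHANES-like
#' morning-fasted adult cohort with a five-class glycemic mixture structure.
#' Class prevalences and the class-conditional means/SDs of FPG, 2-h PG,
#' HbA1c and the FINDRISC total follow the descriptive statistics of the
#' U.S. 2005--2010 screening population the package models (53.75% NGT,
#' 27.08% isolated IFG, 4.37% isolated IGT, 9.51% IFG+IGT, 5.29%
#' undiagnosed diabetes). Missingness and self-reported-diabetes rates
#' default to zero, matching an analysis-ready cohort after exclusions;
#' [exclusion_fixture()] builds the pre-exclusion population instead.
#'
#' @param latent_correlation Gaussian-copula correlation between HbA1c and
#'   the FINDRISC total *within* a glycemic class (default 0: conditional
#'   independence given the class; dependence then enters only through the
#'   class structure).
#' @param dm_fpg_driven_prob Probability that a diabetes-class subject meets
#'   the fasting criterion (FPG >= 126) rather than only the post-load
#'   criterion (2-h PG >= 200).
#' @param missing_rate_hba1c,missing_rate_fpg,missing_rate_pg2h Independent
#'   missingness rates for the three laboratory values.
#' @param self_report_rate Fraction of generated subjects flagged as
#'   self-reported (already diagnosed) diabetes, an excluded stratum.
#' @param weight_meanlog,weight_sdlog Log-normal survey-weight parameters.
#' @param n_cycles Number of pooled survey cycles (weights are tagged with a
#'   cycle in `1:n_cycles`).
#'
#' @return A list of class `cohort_config`.
#' @export
default_cohort_config <- function(latent_correlation = 0,
                                  dm_fpg_driven_prob = 0.5,
                                  missing_rate_hba1c = 0,
                                  missing_rate_fpg = 0,
                                  missing_rate_pg2h = 0,
                                  self_report_rate = 0,
                                  weight_meanlog = 0,
                                  weight_sdlog = 0.5,
                                  n_cycles = 3) {
  stopifnot(
    latent_correlation >= -1, latent_correlation <= 1,
    dm_fpg_driven_prob >= 0, dm_fpg_driven_prob <= 1,
    n_cycles >= 1
  )
  rates <- c(missing_rate_hba1c, missing_rate_fpg, missing_rate_pg2h,
             self_report_rate)
  if (any(rates < 0 | rates > 1)) abort("Rates must lie in [0, 1].")
  class_params <- tibble(
    class = factor(GLYCEMIC_LEVELS, levels = GLYCEMIC_LEVELS),
    prevalence = c(0.5375, 0.2708, 0.0437, 0.0951, 0.0529),
    fpg_mean = c(91.43, 106.15, 93.19, 109.26, 133.67),
    fpg_sd = c(5.70, 5.04, 5.23, 6.67, 42.64),
    pg2h_mean = c(93.35, 104.65, 158.35, 162.79, 234.46),
    pg2h_sd = c(21.80, 21.38, 14.89, 15.74, 76.40),
    hba1c_mean = c(5.28, 5.47, 5.43, 5.63, 6.24),
    hba1c_sd = c(0.35, 0.38, 0.38, 0.38, 1.36),
    findrisc_mean = c(7.28, 9.02, 9.79, 11.32, 11.66),
    findrisc_sd = c(4.39, 4.56, 4.31, 4.17, 4.16)
  )
  class_params$prevalence <- class_params$prevalence /
    sum(class_params$prevalence)
  structure(
    list(
      class_params = class_params,
      latent_correlation = latent_correlation,
      dm_fpg_driven_prob = dm_fpg_driven_prob,
      missing_rate_hba1c = missing_rate_hba1c,
      missing_rate_fpg = missing_rate_fpg,
      missing_rate_pg2h = missing_rate_pg2h,
      self_report_rate = self_report_rate,
      weight_meanlog = weight_meanlog,
      weight_sdlog = weight_sdlog,
      n_cycles = n_cycles
    ),
    class = "cohort_config"
  )
}

# FPG / 2-h PG truncation regions defining each glycemic class. The diabetes
# class is split into two disjoint branches whose union is the full
# "FPG >= 126 or 2-h PG >= 200" region.
glucose_regions <- function() {
  list(
    NGT = list(fpg = c(0, 100), pg2h = c(0, 140)),
    iIFG = list(fpg = c(100, 126), pg2h = c(0, 140)),
    iIGT = list(fpg = c(0, 100), pg2h = c(140, 200)),
    IFG_IGT = list(fpg = c(100, 126), pg2h = c(140, 200)),
    DM_fpg = list(fpg = c(126, Inf), pg2h = c(0, Inf)),
    DM_pg2h = list(fpg = c(0, 126), pg2h = c(200, Inf))
  )
}

# Back-fill raw participant fields consistent with sampled item sub-scores.
# Each points category maps to an interior draw from its raw-value band, so
# re-scoring the raw fields reproduces the sampled sub-scores exactly.
backfill_raw_fields <- function(pts) {
  n <- nrow(pts)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  age <- dplyr::case_when(
    pts$age_pts == 0L ~ runif(n, 20, 44.9),
    pts$age_pts == 2L ~ runif(n, 45, 54.9),
    pts$age_pts == 3L ~ runif(n, 55, 64.9),
    TRUE ~ runif(n, 65, 85)
  )
  bmi <- dplyr::case_when(
    pts$bmi_pts == 0L ~ runif(n, 19, 24.9),
    pts$bmi_pts == 1L ~ runif(n, 25, 30),
    TRUE ~ runif(n, 30.1, 45)
  )
  height <- rtnorm(n, ifelse(sex == "male", 176, 162), 7, 140, 210)
  waist_lo <- ifelse(sex == "male", 94, 80)
  waist_hi <- ifelse(sex == "male", 102, 88)
  waist <- dplyr::case_when(
    pts$waist_pts == 0L ~ runif(n, waist_lo - 25, waist_lo - 0.1),
    pts$waist_pts == 3L ~ runif(n, waist_lo, waist_hi),
    TRUE ~ runif(n, waist_hi + 0.1, waist_hi + 30)
  )
  pa_total <- ifelse(pts$pa_pts == 0L, runif(n, 30, 180), runif(n, 0, 29.9))
  shares <- matrix(stats::rexp(3 * n), ncol = 3)
  shares <- shares / rowSums(shares)
  tibble(
    age = age, sex = sex,
    height = height, weight = bmi * (height / 100)^2,
    waist = waist,
    uses_antihypertensive_med = pts$med_pts == 2L,
    history_high_glucose = pts$glucose_hist_pts == 5L,
    family_history = c("none", "second_degree", "first_degree")[
      match(pts$family_pts, c(0L, 3L, 5L))],
    pa_minutes_commute = pa_total * shares[, 1],
    pa_minutes_recreation = pa_total * shares[, 2],
    pa_minutes_work = pa_total * shares[, 3],
    fruit_veg_daily = pts$fruitveg_pts == 0L
  )
}

# Uniformly sample, per subject, one item-score combination summing to the
# subject's FINDRISC total.
sample_findrisc_components <- function(totals) {
  profiles <- enumerate_findrisc_profiles()
  by_total <- split(seq_len(nrow(profiles)), profiles$findrisc_total)
  rows <- integer(length(totals))
  for (t in unique(totals)) {
    pool <- by_total[[as.character(t)]]
    if (is.null(pool)) {
      abort(sprintf("FINDRISC total %d has no item-score decomposition.", t))
    }
    sel <- totals == t
    rows[sel] <- pool[ceiling(runif(sum(sel)) * length(pool))]
  }
  profiles[rows, , drop = FALSE]
}

#' Generate a synthetic NHANES-like screening cohort
#'
#' Draws `n` participants from the five-class glycemic mixture described by a
#' [default_cohort_config()]: each subject receives a glycemic class from the
#' class prevalences; FPG and 2-h PG from class-conditional truncated normals
#' whose truncation region is exactly the class's defining glucose region (so
#' every record classifies back to its assigned class by construction);
#' HbA1c from the class-conditional normal truncated at zero; and a FINDRISC
#' total from the class-conditional rounded truncated normal on 0--26, whose
#' eight item sub-scores are then sampled uniformly among the combinations
#' summing to that total and back-filled into raw questionnaire and
#' anthropometric fields consistent with the sub-scores. Survey weights,
#' cycles, fasting times, optional missingness and an optional
#' self-reported-diabetes stratum complete the record.
#'
#' @param n Number of participants.
#' @param config A `cohort_config`; defaults to [default_cohort_config()].
#' @param seed Optional integer seed; the same (n, config, seed) always
#'   yields an identical cohort.
#'
#' @return A tibble with one row per participant: identifier, the raw
#'   FINDRISC inputs, `fpg`, `pg2h`, `hba1c`, `fasting_hours`,
#'   `self_reported_diabetes`, `survey_weight`, `survey_cycle`, the sampled
#'   `findrisc_total`, and the generator-truth `true_class`.
#' @examples
#' cohort <- generate_cohort(500, seed = 1)
#' table(cohort$true_class)
#' @export
generate_cohort <- function(n, config = default_cohort_config(),
                            seed = NULL) {
  stopifnot(inherits(config, "cohort_config"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  cp <- config$class_params
  if (n == 0) {
    return(empty_cohort())
  }
  cls <- sample(as.character(cp$class), n, replace = TRUE,
                prob = cp$prevalence)
  fpg <- numeric(n)
  pg2h <- numeric(n)
  hba1c <- numeric(n)
  total <- integer(n)
  regions <- glucose_regions()
  rho <- config$latent_correlation
  for (k in seq_len(nrow(cp))) {
    cl <- as.character(cp$class[k])
    sel <- which(cls == cl)
    m <- length(sel)
    if (m == 0) next
    if (cl == "DM") {
      fpg_driven <- runif(m) < config$dm_fpg_driven_prob
      for (branch in c(TRUE, FALSE)) {
        b <- sel[fpg_driven == branch]
        if (length(b) == 0) next
        reg <- if (branch) regions$DM_fpg else regions$DM_pg2h
        fpg[b] <- rtnorm(length(b), cp$fpg_mean[k], cp$fpg_sd[k],
                         reg$fpg[1], reg$fpg[2])
        pg2h[b] <- rtnorm(length(b), cp$pg2h_mean[k], cp$pg2h_sd[k],
                          reg$pg2h[1], reg$pg2h[2])
      }
    } else {
      reg <- regions[[cl]]
      fpg[sel] <- rtnorm(m, cp$fpg_mean[k], cp$fpg_sd[k],
                         reg$fpg[1], reg$fpg[2])
      pg2h[sel] <- rtnorm(m, cp$pg2h_mean[k], cp$pg2h_sd[k],
                          reg$pg2h[1], reg$pg2h[2])
    }
    # Gaussian copula between HbA1c and FINDRISC within the class
    z1 <- stats::rnorm(m)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(m)
    u_h <- pnorm(z1)
    u_f <- pnorm(z2)
    p0 <- pnorm(0, cp$hba1c_mean[k], cp$hba1c_sd[k])
    hba1c[sel] <- qnorm(p0 + u_h * (1 - p0),
                        cp$hba1c_mean[k], cp$hba1c_sd[k])
    pmf <- findrisc_total_pmf(cp$findrisc_mean[k], cp$findrisc_sd[k])
    cdf <- cumsum(pmf$prob)
    total[sel] <- pmf$total[findInterval(u_f, cdf, left.open = TRUE) + 1L]
  }
  pts <- sample_findrisc_components(total)
  raw <- backfill_raw_fields(pts)
  cohort <- bind_cols(
    tibble(id = sprintf("S%06d", seq_len(n))),
    raw,
    tibble(
      fpg = fpg, pg2h = pg2h, hba1c = hba1c,
      fasting_hours = runif(n, 9, 16),
      self_reported_diabetes = runif(n) < config$self_report_rate,
      survey_weight = rlnorm(n, config$weight_meanlog, config$weight_sdlog),
      survey_cycle = sample(seq_len(config$n_cycles), n, replace = TRUE),
      findrisc_total = total,
      true_class = factor(cls, levels = GLYCEMIC_LEVELS)
    )
  )
  # missingness applied last so the complete-data truth is drawn identically
  if (config$missing_rate_hba1c > 0) {
    cohort$hba1c[runif(n) < config$missing_rate_hba1c] <- NA_real_
  }
  if (config$missing_rate_fpg > 0) {
    cohort$fpg[runif(n) < config$missing_rate_fpg] <- NA_real_
  }
  if (config$missing_rate_pg2h > 0) {
    cohort$pg2h[runif(n) < config$missing_rate_pg2h] <- NA_real_
  }
  cohort
}

empty_cohort <- function() {
  tibble(
    id = character(), age = numeric(), sex = character(),
    height = numeric(), weight = numeric(), waist = numeric(),
    uses_antihypertensive_med = logical(), history_high_glucose = logical(),
    family_history = character(), pa_minutes_commute = numeric(),
    pa_minutes_recreation = numeric(), pa_minutes_work = numeric(),
    fruit_veg_daily = logical(), fpg = numeric(), pg2h = numeric(),
    hba1c = numeric(), fasting_hours = numeric(),
    self_reported_diabetes = logical(), survey_weight = numeric(),
    survey_cycle = integer(), findrisc_total = integer(),
    true_class = factor(levels = GLYCEMIC_LEVELS)
  )
}

#' Build a cohort reproducing a known exclusion cascade
#'
#' Generates a clean cohort of `n_total` participants and then plants
#' disjoint defect groups of exactly the requested sizes (missing HbA1c,
#' missing FPG, missing 2-h PG, self-reported diabetes) so that
#' [apply_exclusions()] reproduces the requested per-step tallies exactly and
#' retains `n_total - sum(counts)` records.
#'
#' @param n_total Total number of eligible records.
#' @param counts Named integer vector of defect-group sizes, in cascade
#'   order: `missing_hba1c`, `missing_fpg`, `missing_pg2h`,
#'   `self_reported_diabetes`.
#' @inheritParams generate_cohort
#'
#' @return A cohort tibble of `n_total` rows.
#' @examples
#' fx <- exclusion_fixture(seed = 1)
#' nrow(apply_exclusions(fx)) # 3886
#' @export
exclusion_fixture <- function(n_total = 4893,
                              counts = c(missing_hba1c = 87,
                                         missing_fpg = 15,
                                         missing_pg2h = 806,
                                         self_reported_diabetes = 99),
                              config = default_cohort_config(),
                              seed = NULL) {
  expected <- c("missing_hba1c", "missing_fpg", "missing_pg2h",
                "self_reported_diabetes")
  if (!identical(names(counts), expected)) {
    abort(sprintf("`counts` must be named, in order: %s.",
                  paste(expected, collapse = ", ")))
  }
  counts <- as.integer(counts)
  if (any(counts < 0) || sum(counts) > n_total) {
    abort("Defect counts must be >= 0 and sum to at most `n_total`.")
  }
  cohort <- generate_cohort(n_total, config = config, seed = seed)
  bounds <- cumsum(c(0, counts))
  grp <- function(j) (bounds[j] + 1):bounds[j + 1]
  if (counts[1] > 0) cohort$hba1c[grp(1)] <- NA_real_
  if (counts[2] > 0) cohort$fpg[grp(2)] <- NA_real_
  if (counts[3] > 0) cohort$pg2h[grp(3)] <- NA_real_
  if (counts[4] > 0) cohort$self_reported_diabetes[grp(4)] <- TRUE
  cohort[sample(n_total), , drop = FALSE]
}
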