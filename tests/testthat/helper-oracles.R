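# Independent oracles used across the suite. Everything here is computed
# from first principles (closed forms, brute-force enumeration) and never
# calls the package code paths it checks.

# --- truncated-normal closed forms -----------------------------------------

oracle_tn_mean <- function(mu, sd, lo = -Inf, hi = Inf) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- pnorm(b) - pnorm(a)
  mu + sd * (dnorm(a) - dnorm(b)) / z
}

oracle_tn_sd <- function(mu, sd, lo = -Inf, hi = Inf) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- pnorm(b) - pnorm(a)
  da <- dnorm(a); db <- dnorm(b)
  ta <- if (is.finite(a)) a * da else 0
  tb <- if (is.finite(b)) b * db else 0
  v <- sd^2 * (1 + (ta - tb) / z - ((da - db) / z)^2)
  sqrt(v)
}

# P(X >= q) for X ~ N(mu, sd) truncated to [lo, hi]
oracle_tn_exceed <- function(q, mu, sd, lo = -Inf, hi = Inf) {
  z <- pnorm(hi, mu, sd) - pnorm(lo, mu, sd)
  q <- max(q, lo)
  (pnorm(hi, mu, sd) - pnorm(q, mu, sd)) / z
}

# --- FINDRISC total: discretized truncated normal --------------------------

# Enumerated independently of the package's point tables.
oracle_findrisc_totals <- function() {
  grid <- expand.grid(
    a = c(0, 2, 3, 4), b = c(0, 1, 3), c = c(0, 3, 4), d = c(0, 2),
    e = c(0, 1), f = c(0, 2), g = c(0, 5), h = c(0, 3, 5)
  )
  rowSums(grid)
}

oracle_findrisc_pmf <- function(mu, sd) {
  totals <- sort(unique(oracle_findrisc_totals()))
  p <- pnorm(totals + 0.5, mu, sd) - pnorm(totals - 0.5, mu, sd)
  data.frame(total = totals, prob = p / sum(p))
}

oracle_findrisc_mean <- function(mu, sd) {
  pmf <- oracle_findrisc_pmf(mu, sd)
  sum(pmf$total * pmf$prob)
}

oracle_findrisc_sd <- function(mu, sd) {
  pmf <- oracle_findrisc_pmf(mu, sd)
  m <- sum(pmf$total * pmf$prob)
  sqrt(sum(pmf$total^2 * pmf$prob) - m^2)
}

oracle_findrisc_exceed <- function(q, mu, sd) {
  pmf <- oracle_findrisc_pmf(mu, sd)
  sum(pmf$prob[pmf$total >= q])
}

# --- generator-truth operating points --------------------------------------

# Expected sensitivity/specificity of hba1c >= cut (target: diabetes) under
# the default class mixture. HbA1c is a per-class normal truncated at 0.
oracle_hba1c_operating_point <- function(config, cut,
                                         target = "diabetes") {
  cp <- config$class_params
  exceed <- mapply(function(mu, sd) oracle_tn_exceed(cut, mu, sd, lo = 0),
                   cp$hba1c_mean, cp$hba1c_sd)
  names(exceed) <- as.character(cp$class)
  prev <- stats::setNames(cp$prevalence, as.character(cp$class))
  if (target == "diabetes") {
    se <- exceed[["DM"]]
    w <- prev[names(prev) != "DM"]
    sp <- 1 - sum(w * exceed[names(w)]) / sum(w)
  } else { # prediabetes: DM excluded, disease = the three impaired classes
    dis <- c("iIFG", "iIGT", "IFG_IGT")
    wd <- prev[dis]
    se <- sum(wd * exceed[dis]) / sum(wd)
    sp <- 1 - exceed[["NGT"]]
  }
  c(sensitivity = unname(se), specificity = unname(sp))
}

oracle_findrisc_operating_point <- function(config, cut,
                                            target = "diabetes") {
  cp <- config$class_params
  exceed <- mapply(function(mu, sd) oracle_findrisc_exceed(cut, mu, sd),
                   cp$findrisc_mean, cp$findrisc_sd)
  names(exceed) <- as.character(cp$class)
  prev <- stats::setNames(cp$prevalence, as.character(cp$class))
  if (target == "diabetes") {
    se <- exceed[["DM"]]
    w <- prev[names(prev) != "DM"]
    sp <- 1 - sum(w * exceed[names(w)]) / sum(w)
  } else {
    dis <- c("iIFG", "iIGT", "IFG_IGT")
    wd <- prev[dis]
    se <- sum(wd * exceed[dis]) / sum(wd)
    sp <- 1 - exceed[["NGT"]]
  }
  c(sensitivity = unname(se), specificity = unname(sp))
}

# --- brute-force ROC -------------------------------------------------------

# O(n^2) operating points by explicit threshold enumeration (positivity >=).
oracle_roc_points <- function(scores, disease) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  do.call(rbind, lapply(thr, function(t) {
    pos <- scores >= t
    data.frame(
      threshold = t,
      sensitivity = sum(pos & disease) / sum(disease),
      specificity = sum(!pos & !disease) / sum(!disease)
    )
  }))
}

# Pair-counting AUC, ties counting one half.
oracle_auc_pairs <- function(scores, disease) {
  x <- scores[disease]
  y <- scores[!disease]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# --- small cohort builders -------------------------------------------------

# Minimal scored/classified cohort from explicit vectors.
toy_cohort <- function(findrisc_total, hba1c, class,
                       weight = rep(1, length(findrisc_total))) {
  tibble::tibble(
    findrisc_total = findrisc_total,
    hba1c = hba1c,
    glycemic_class = factor(class, levels = c("NGT", "iIFG", "iIGT",
                                              "IFG_IGT", "DM")),
    age = rep(50, length(findrisc_total)),
    survey_weight = weight
  )
}

# A raw participant row with low-risk defaults, overridable per test.
toy_participant <- function(...) {
  base <- tibble::tibble(
    age = 30, sex = "male", height = 180, weight = 71.28, waist = 80,
    uses_antihypertensive_med = FALSE, history_high_glucose = FALSE,
    family_history = "none", pa_minutes_commute = 20,
    pa_minutes_recreation = 20, pa_minutes_work = 0,
    fruit_veg_daily = TRUE
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}
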