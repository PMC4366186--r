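# Weighted empirical operating points over all distinct score thresholds.
# Positivity is score >= threshold; the +Inf pseudo-threshold anchors the
# curve at (0, 0) and the minimum observed score yields (1, 1).
roc_points <- function(scores, disease, weights = NULL) {
  if (length(scores) != length(disease)) {
    abort("`scores` and `disease` must have the same length.")
  }
  if (is.null(weights)) weights <- rep(1, length(scores))
  if (any(is.na(scores)) || any(is.na(disease)) || any(is.na(weights))) {
    abort("scores, disease status and weights must not contain missing values.")
  }
  if (any(weights <= 0)) abort("`weights` must be positive.")
  wd <- sum(weights[disease])
  wn <- sum(weights[!disease])
  if (wd == 0 || wn == 0) {
    abort("ROC curve undefined: need at least one diseased and one non-diseased subject.")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  w_pos <- cumsum(weights[ord] * disease[ord])
  w_neg <- cumsum(weights[ord] * !disease[ord])
  # last index of each tied block = cumulative counts at score >= threshold
  runs <- rle(s)
  thresholds <- c(Inf, runs$values)
  idx <- cumsum(runs$lengths)
  tibble(
    threshold = thresholds,
    sensitivity = c(0, w_pos[idx] / wd),
    specificity = c(1, 1 - w_neg[idx] / wn)
  )
}

#' Empirical ROC curve over all observed score thresholds
#'
#' Builds the (optionally survey-weighted) empirical receiver operating
#' characteristic curve of a continuous or ordinal score against a binary
#' reference standard. One operating point is produced per distinct observed
#' score value, with positivity defined as score >= threshold, plus the
#' (0, 0) anchor at an infinite threshold; the lowest threshold classifies
#' everyone positive and lands at (1, 1).
#'
#' @param data Cohort data frame.
#' @param score Unquoted column holding the score (higher = more diseased).
#' @param truth Unquoted logical column or expression giving reference
#'   disease status, evaluated within `data`.
#' @param weights Optional unquoted column of positive survey weights.
#'
#' @return A tibble of class `roc_curve` with columns `threshold`
#'   (descending), `sensitivity` and `specificity` (proportions). Use
#'   [auc_trapezoidal()], [glance()] or [autoplot()] on it.
#' @export
empirical_roc <- function(data, score, truth, weights = NULL) {
  data <- as_tibble(data)
  scores <- eval_tidy(enquo(score), data)
  disease <- as.logical(eval_tidy(enquo(truth), data))
  wq <- enquo(weights)
  w <- if (quo_is_null(wq)) NULL else eval_tidy(wq, data)
  pts <- roc_points(scores, disease, w)
  structure(pts,
            class = c("roc_curve", class(pts)),
            n_pos = sum(as.logical(disease)),
            n_neg = sum(!as.logical(disease)))
}

#' Area under an ROC curve by trapezoidal integration
#'
#' Integrates sensitivity over the false-positive rate along the empirical
#' curve. 0.5 is chance performance; 1.0 is perfect discrimination.
#'
#' @param curve A `roc_curve` from [empirical_roc()].
#' @return AUC in \[0, 1\].
#' @export
auc_trapezoidal <- function(curve) {
  if (!inherits(curve, "roc_curve")) {
    abort("`curve` must be a `roc_curve` from `empirical_roc()`.")
  }
  fpr <- 1 - curve$specificity
  tpr <- curve$sensitivity
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' The probability that a randomly chosen diseased subject outscores a
#' randomly chosen non-diseased one, with ties counting one half; with
#' weights, pairs are weighted by the product of subject weights. Equals the
#' trapezoidal area under the empirical ROC curve of the same data.
#'
#' @inheritParams empirical_roc
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(data, score, truth, weights = NULL) {
  data <- as_tibble(data)
  scores <- eval_tidy(enquo(score), data)
  disease <- as.logical(eval_tidy(enquo(truth), data))
  wq <- enquo(weights)
  w <- if (quo_is_null(wq)) rep(1, length(scores)) else eval_tidy(wq, data)
  if (any(w <= 0)) abort("`weights` must be positive.")
  wd_tot <- sum(w[disease])
  wn_tot <- sum(w[!disease])
  if (wd_tot == 0 || wn_tot == 0) {
    abort("AUC undefined: need both diseased and non-diseased subjects.")
  }
  ord <- order(scores)
  s <- scores[ord]; d <- disease[ord]; w <- w[ord]
  grp <- cumsum(c(TRUE, diff(s) != 0)) # run id of tied score blocks
  nd_by_grp <- rowsum(w * !d, grp)[, 1]
  nd_below <- cumsum(c(0, utils::head(nd_by_grp, -1)))
  # for each diseased subject: non-diseased weight strictly below + half ties
  contrib <- w * d * (nd_below[grp] + 0.5 * nd_by_grp[grp])
  sum(contrib) / (wd_tot * wn_tot)
}

# Placement values (midrank form). Returns list with V10 (per diseased) and
# V01 (per non-diseased); mean(V10) = mean(V01) = AUC.
delong_placements <- function(scores, disease) {
  x <- scores[disease]
  y <- scores[!disease]
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) {
    abort("DeLong statistics undefined: need both classes present.")
  }
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' DeLong variance of a single empirical AUC
#'
#' Nonparametric variance estimate of the Mann-Whitney AUC from placement
#' values: `var(V10)/m + var(V01)/n` with `m` diseased and `n` non-diseased
#' subjects (unit weights).
#'
#' @inheritParams empirical_roc
#' @return A one-row tibble with `auc`, `variance`, `m`, `n`.
#' @export
auc_variance_delong <- function(data, score, truth) {
  data <- as_tibble(data)
  scores <- eval_tidy(enquo(score), data)
  disease <- as.logical(eval_tidy(enquo(truth), data))
  pl <- delong_placements(scores, disease)
  tibble(auc = pl$auc,
         variance = var(pl$v10) / pl$m + var(pl$v01) / pl$n,
         m = pl$m, n = pl$n)
}

#' DeLong's test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same subjects against the
#' same reference standard, using DeLong's nonparametric covariance of the
#' paired placement values. The statistic `(AUC_a - AUC_b)^2 / var` is
#' referred to a 1-df chi-square distribution (equivalently, the square of
#' the usual z statistic).
#'
#' @param data Cohort data frame.
#' @param score_a,score_b Unquoted columns holding the two scores.
#' @param truth Unquoted logical column or expression giving reference
#'   disease status, evaluated within `data`.
#'
#' @return An object of class `auc_comparison`; see [tidy()] / [glance()]
#'   methods. Identical score vectors give `chi_square = 0`, `p_value = 1`.
#' @export
delong_compare <- function(data, score_a, score_b, truth) {
  data <- as_tibble(data)
  sa <- eval_tidy(enquo(score_a), data)
  sb <- eval_tidy(enquo(score_b), data)
  disease <- as.logical(eval_tidy(enquo(truth), data))
  pa <- delong_placements(sa, disease)
  pb <- delong_placements(sb, disease)
  m <- pa$m; n <- pa$n
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- pa$auc - pb$auc
  if (var_diff <= 0) {
    if (abs(diff) < sqrt(.Machine$double.eps)) {
      chi <- 0
      p <- 1
    } else {
      abort("Degenerate comparison: zero variance with unequal AUCs.")
    }
  } else {
    chi <- diff^2 / var_diff
    p <- pchisq(chi, df = 1, lower.tail = FALSE)
  }
  structure(
    list(auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff,
         chi_square = chi, p_value = p, m = m, n = n),
    class = "auc_comparison"
  )
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf(
    "DeLong comparison of correlated AUCs\n  AUC(a) = %.4f  AUC(b) = %.4f\n  chi-square(1 df) = %.3f, p = %.4g\n",
    x$auc_a, x$auc_b, x$chi_square, x$p_value))
  invisible(x)
}

#' @rdname delong_compare
#' @param x An `auc_comparison` object.
#' @param ... Unused.
#' @export
tidy.auc_comparison <- function(x, ...) {
  tibble(auc_a = x$auc_a, auc_b = x$auc_b, estimate = x$auc_a - x$auc_b,
         chi_square = x$chi_square, df = 1, p_value = x$p_value)
}

#' @rdname delong_compare
#' @export
glance.auc_comparison <- function(x, ...) {
  tibble(chi_square = x$chi_square, p_value = x$p_value,
         n_disease = x$m, n_control = x$n)
}

#' Optimal cutoff by shortest ROC distance
#'
#' Returns the threshold whose operating point minimises the Euclidean
#' distance to perfect classification, `sqrt((1-se)^2 + (1-sp)^2)`. Ties are
#' broken toward the higher threshold (fewer screen-positives).
#'
#' @param curve A `roc_curve` from [empirical_roc()].
#' @return The optimal threshold (same units as the score).
#' @export
optimal_cutoff_by_distance <- function(curve) {
  if (!inherits(curve, "roc_curve")) {
    abort("`curve` must be a `roc_curve` from `empirical_roc()`.")
  }
  interior <- curve[is.finite(curve$threshold), , drop = FALSE]
  if (nrow(interior) == 0) abort("Curve has no interior operating points.")
  d <- roc_distance(100 * interior$sensitivity, 100 * interior$specificity)
  best <- which(d == min(d))
  max(interior$threshold[best])
}

#' @rdname empirical_roc
#' @param x A `roc_curve`.
#' @param ... Unused.
#' @export
tidy.roc_curve <- function(x, ...) {
  as_tibble(unclass_roc(x))
}

#' @rdname empirical_roc
#' @export
glance.roc_curve <- function(x, ...) {
  tibble(
    auc = auc_trapezoidal(x),
    optimal_cutoff = optimal_cutoff_by_distance(x),
    n_pos = attr(x, "n_pos") %||% NA_integer_,
    n_neg = attr(x, "n_neg") %||% NA_integer_,
    n_thresholds = sum(is.finite(x$threshold))
  )
}

unclass_roc <- function(x) {
  class(x) <- setdiff(class(x), "roc_curve")
  x
}

#' @rdname empirical_roc
#' @param object A `roc_curve`.
#' @export
autoplot.roc_curve <- function(object, ...) {
  df <- tidy(object)
  df$fpr <- 1 - df$specificity
  ggplot2::ggplot(df, ggplot2::aes(x = fpr, y = sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("Empirical ROC (AUC = %.3f)",
                                  auc_trapezoidal(object))) +
    ggplot2::theme_minimal()
}
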