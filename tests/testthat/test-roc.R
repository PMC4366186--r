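test_that("empirical operating points match brute-force threshold enumeration", {
  scores <- c(1, 3, 3, 5, 7, 7, 8, 2)
  disease <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)
  curve <- empirical_roc(tibble::tibble(s = scores, d = disease), s, d)
  want <- oracle_roc_points(scores, disease)
  expect_equal(curve$threshold, want$threshold)
  expect_equal(curve$sensitivity, want$sensitivity)
  expect_equal(curve$specificity, want$specificity)
  # anchors
  expect_equal(curve$sensitivity[1], 0)
  expect_equal(curve$specificity[1], 1)
  expect_equal(curve$sensitivity[nrow(curve)], 1)
  expect_equal(curve$specificity[nrow(curve)], 0)
  # AUC equals pair counting on the same data
  expect_equal(auc_trapezoidal(curve), oracle_auc_pairs(scores, disease))
})

test_that("degenerate score patterns give the expected curves", {
  sep <- tibble::tibble(s = c(1, 2, 10, 11), d = c(FALSE, FALSE, TRUE, TRUE))
  curve <- empirical_roc(sep, s, d)
  expect_true(any(curve$sensitivity == 1 & curve$specificity == 1))
  expect_equal(auc_trapezoidal(curve), 1)

  flat <- tibble::tibble(s = rep(4, 6), d = rep(c(TRUE, FALSE), 3))
  curve2 <- empirical_roc(flat, s, d)
  expect_equal(nrow(curve2), 2L)
  expect_equal(auc_trapezoidal(curve2), 0.5)

  expect_error(empirical_roc(tibble::tibble(s = 1:3, d = rep(TRUE, 3)),
                             s, d), "non-diseased")
})

test_that("trapezoidal and rank AUC agree to numerical precision", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(8:40, 1)
    df <- tibble::tibble(
      s = sample(0:12, n, replace = TRUE), # heavy ties
      d = c(TRUE, FALSE, runif(n - 2) < 0.4)
    )
    a1 <- auc_trapezoidal(empirical_roc(df, s, d))
    a2 <- auc_rank(df, s, d)
    expect_equal(a1, a2, tolerance = 1e-12)
  }
})

test_that("weighted AUC reduces to unweighted under unit weights and matches pair weighting", {
  set.seed(7)
  df <- tibble::tibble(
    s = sample(0:10, 30, replace = TRUE),
    d = runif(30) < 0.4,
    w = runif(30, 0.2, 3)
  )
  expect_equal(auc_rank(df, s, d, w = rep(1, 30)), auc_rank(df, s, d))
  # weighted pair-counting oracle
  x <- df$s[df$d]; wx <- df$w[df$d]
  y <- df$s[!df$d]; wy <- df$w[!df$d]
  num <- sum(outer(wx, wy) * outer(x, y, function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(auc_rank(df, s, d, w), num / (sum(wx) * sum(wy)))
  # weighted empirical curve integrates to the same area
  expect_equal(auc_trapezoidal(empirical_roc(df, s, d, w)),
               auc_rank(df, s, d, w), tolerance = 1e-12)
})

test_that("AUC is invariant under monotone transforms and flips with labels", {
  set.seed(9)
  df <- tibble::tibble(s = rnorm(60), d = runif(60) < 0.35)
  a <- auc_rank(df, s, d)
  expect_equal(auc_rank(dplyr::mutate(df, s = exp(2 * s)), s, d), a)
  expect_equal(auc_rank(dplyr::mutate(df, s = rank(s)), s, d), a)
  expect_equal(auc_rank(df, s, !d), 1 - a)
})

test_that("DeLong comparison is null for identical scores and symmetric in its arguments", {
  set.seed(3)
  df <- tibble::tibble(a = rnorm(50), d = runif(50) < 0.5)
  df$b <- df$a
  same <- delong_compare(df, a, b, d)
  expect_equal(same$chi_square, 0)
  expect_equal(same$p_value, 1)

  df$b <- df$a + rnorm(50)
  ab <- delong_compare(df, a, b, d)
  ba <- delong_compare(df, b, a, d)
  expect_equal(ab$chi_square, ba$chi_square)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(tidy(ab)$estimate, -tidy(ba)$estimate)
})

test_that("DeLong chi-square agrees with an independent implementation", {
  set.seed(42)
  n <- 150
  d <- runif(n) < 0.4
  a <- rnorm(n, mean = ifelse(d, 1, 0))
  b <- 0.5 * a + rnorm(n, mean = ifelse(d, 0.6, 0))
  df <- tibble::tibble(a = a, b = b, d = d)
  ours <- delong_compare(df, a, b, d)
  ref <- pROC::roc.test(
    pROC::roc(d, a, quiet = TRUE, direction = "<"),
    pROC::roc(d, b, quiet = TRUE, direction = "<"),
    method = "delong")
  expect_equal(ours$chi_square, unname(ref$statistic)^2, tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(sort(c(ours$auc_a, ours$auc_b)),
               sort(as.numeric(ref$estimate)), tolerance = 1e-12)
})

test_that("single-AUC DeLong variance tracks a hand placement computation", {
  scores <- c(2, 4, 6, 1, 3, 5)
  disease <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  # hand placement values: V10_i = share of controls below each case
  v10 <- c(1 / 3, 2 / 3, 1)
  v01 <- c(1, 2 / 3, 1 / 3)
  out <- auc_variance_delong(tibble::tibble(s = scores, d = disease), s, d)
  expect_equal(out$auc, mean(v10))
  expect_equal(out$variance, var(v10) / 3 + var(v01) / 3)
})

test_that("the shortest-distance cutoff matches an exhaustive scan and prefers higher thresholds on ties", {
  scores <- c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)
  disease <- c(FALSE, FALSE, FALSE, TRUE, TRUE,
               FALSE, FALSE, TRUE, TRUE, TRUE)
  df <- tibble::tibble(s = scores, d = disease)
  curve <- empirical_roc(df, s, d)
  pts <- oracle_roc_points(scores, disease)
  pts <- pts[is.finite(pts$threshold), ]
  d_all <- sqrt((1 - pts$sensitivity)^2 + (1 - pts$specificity)^2)
  best <- max(pts$threshold[d_all == min(d_all)])
  expect_equal(optimal_cutoff_by_distance(curve), best)

  # a perfect interior point wins outright
  sep <- tibble::tibble(s = c(1, 2, 9, 10), d = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(optimal_cutoff_by_distance(empirical_roc(sep, s, d)), 9)

  # exact tie between two thresholds resolves to the higher one
  tie <- tibble::tibble(s = c(1, 2, 3, 4), d = c(FALSE, TRUE, FALSE, TRUE))
  pts_tie <- oracle_roc_points(tie$s, tie$d)
  pts_tie <- pts_tie[is.finite(pts_tie$threshold), ]
  d_tie <- sqrt((1 - pts_tie$sensitivity)^2 + (1 - pts_tie$specificity)^2)
  expect_equal(optimal_cutoff_by_distance(empirical_roc(tie, s, d)),
               max(pts_tie$threshold[d_tie == min(d_tie)]))
})

test_that("roc_curve accessors and plot build from the curve", {
  df <- tibble::tibble(s = c(1, 3, 3, 5, 7, 7, 8, 2),
                       d = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE,
                             FALSE))
  curve <- empirical_roc(df, s, d)
  g <- glance(curve)
  expect_equal(g$auc, auc_trapezoidal(curve))
  expect_equal(g$n_pos, 4L)
  expect_equal(g$n_neg, 4L)
  expect_s3_class(tidy(curve), "tbl_df")
  expect_s3_class(autoplot(curve), "ggplot")
})
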