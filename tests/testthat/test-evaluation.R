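test_that("leaf tests use >= positivity and combinations apply OR/AND", {
  data <- toy_cohort(findrisc_total = c(9, 4, 8), hba1c = c(6.4, 5.8, 6.49),
                     class = c("DM", "NGT", "NGT"))
  expect_equal(apply_test(findrisc_test(9), data), c(TRUE, FALSE, FALSE))
  expect_equal(apply_test(hba1c_test(6.5), data), c(FALSE, FALSE, FALSE))
  both <- parallel_or(findrisc_test(9), hba1c_test(5.7))
  expect_equal(apply_test(both, data), c(TRUE, TRUE, TRUE))
  seq_test <- serial_and(findrisc_test(8), hba1c_test(5.7))
  expect_equal(apply_test(seq_test, data), c(TRUE, FALSE, TRUE))
})

test_that("tests with absent or missing inputs fail loudly", {
  data <- toy_cohort(findrisc_total = 5, hba1c = NA_real_, class = "NGT")
  expect_error(apply_test(hba1c_test(6.5), data), "missing")
  expect_error(apply_test(findrisc_test(9), data[, "hba1c"]), "absent")
})

test_that("confusion counts match brute-force tallies, weighted and not", {
  cc <- build_confusion(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(unlist(cc), c(tp = 1, fp = 0, tn = 1, fn = 0))
  cc_w <- build_confusion(c(TRUE, FALSE), c(TRUE, FALSE), weights = c(2, 3))
  expect_equal(cc_w$tp, 2)
  expect_equal(cc_w$tn, 3)

  set.seed(5)
  test <- runif(6) > 0.5
  disease <- runif(6) > 0.5
  w <- runif(6, 0.5, 2)
  cc6 <- build_confusion(test, disease, w)
  expect_equal(cc6$tp, sum(w * (test & disease)))
  expect_equal(cc6$fp, sum(w * (test & !disease)))
  expect_equal(cc6$tn, sum(w * (!test & !disease)))
  expect_equal(cc6$fn, sum(w * (!test & disease)))
  expect_error(build_confusion(test, disease[1:3]), "length")
})

test_that("metrics derive correctly from a hand-built 2x2 table", {
  m <- metrics_from_confusion(tibble::tibble(tp = 8, fn = 2, fp = 30,
                                             tn = 60))
  expect_equal(m$sensitivity, 80)
  expect_equal(m$specificity, 100 * 60 / 90)
  expect_equal(m$ppv, 100 * 8 / 38)
  expect_equal(m$npv, 100 * 60 / 62)
  expect_equal(m$sum, m$sensitivity + m$specificity)
  expect_equal(m$roc_distance, roc_distance(m$sensitivity, m$specificity))
  expect_equal(m$fraction_positive, 100 * 38 / 100)

  balanced <- metrics_from_confusion(tibble::tibble(tp = 3, fn = 3, fp = 4,
                                                    tn = 4))
  expect_equal(balanced$sensitivity, 50)
  expect_equal(balanced$specificity, 50)

  perfect <- metrics_from_confusion(tibble::tibble(tp = 5, fn = 0, fp = 0,
                                                   tn = 5))
  expect_equal(perfect$roc_distance, 0)
  expect_error(metrics_from_confusion(tibble::tibble(tp = 0, fn = 0, fp = 1,
                                                     tn = 1)), "diseased")
})

test_that("the ROC shortest-distance statistic matches hand values", {
  expect_equal(round(roc_distance(79.12, 51.40), 2), 0.53)
  expect_equal(round(roc_distance(60.18, 61.40), 2), 0.55)
  expect_equal(roc_distance(100, 100), 0)
  expect_equal(roc_distance(0, 0), sqrt(2))
  expect_error(roc_distance(101, 50), "0, 100")
})

test_that("prevalence-adjusted predictive values follow Bayes' rule", {
  pv <- prevalence_adjusted_predictive_values(79.12, 51.40, 0.07)
  expect_equal(pv$ppv, 100 * 0.7912 * 0.07 /
                 (0.7912 * 0.07 + (1 - 0.514) * 0.93))
  expect_equal(round(pv$ppv, 1), 10.9)
  expect_equal(round(pv$npv, 1), 97.0)
  expect_equal(
    unlist(prevalence_adjusted_predictive_values(100, 100, 0.3)),
    c(ppv = 100, npv = 100))
  expect_equal(
    unlist(prevalence_adjusted_predictive_values(50, 50, 0.5)),
    c(ppv = 50, npv = 50))
  expect_error(prevalence_adjusted_predictive_values(80, 60, 0), "proportion")
})

test_that("the population screening-positive fraction is se*p + (1-sp)(1-p)", {
  expect_equal(round(population_positive_fraction(79.12, 51.40, 0.07), 1),
               50.7)
  expect_equal(round(population_positive_fraction(94.14, 20.90, 0.07), 1),
               80.2)
  expect_equal(population_positive_fraction(100, 100, 0.1), 10)
})

test_that("adjusted predictive values at the sample prevalence equal the crude ones", {
  cohort <- generate_cohort(3000, seed = 21)
  cohort <- add_glycemic_class(cohort)
  crude <- evaluate_model(cohort, findrisc_test(9), "diabetes")
  p <- mean(cohort$glycemic_class == "DM")
  adj <- prevalence_adjusted_predictive_values(
    crude$sensitivity, crude$specificity, p)
  expect_equal(adj$ppv, crude$ppv, tolerance = 1e-10)
  expect_equal(adj$npv, crude$npv, tolerance = 1e-10)
  expect_equal(population_positive_fraction(
    crude$sensitivity, crude$specificity, p),
    crude$fraction_positive, tolerance = 1e-10)
})

test_that("degenerate and trivial tests hit the metric extremes", {
  cohort <- add_glycemic_class(generate_cohort(400, seed = 8))
  everyone <- evaluate_model(cohort, findrisc_test(0), "diabetes")
  expect_equal(everyone$sensitivity, 100)
  expect_equal(everyone$specificity, 0)
  noone <- evaluate_model(cohort, hba1c_test(1e6), "diabetes")
  expect_equal(noone$sensitivity, 0)
  expect_equal(noone$specificity, 100)
})

test_that("diabetes cases are excluded before pre-diabetes metrics", {
  data <- toy_cohort(
    findrisc_total = c(10, 10, 2, 2, 20),
    hba1c = c(5.8, 5.5, 5.2, 5.9, 7.5),
    class = c("iIFG", "iIGT", "NGT", "NGT", "DM")
  )
  out <- evaluate_model(data, findrisc_test(9), "prediabetes")
  expect_equal(out$n, 4L) # the DM row is gone
  expect_equal(out$n_disease, 2L)
  expect_equal(out$sensitivity, 100)
  expect_equal(out$specificity, 100)
})

test_that("sensitivity falls and specificity rises as the cutoff increases", {
  cohort <- add_glycemic_class(generate_cohort(4000, seed = 31))
  sweep <- sweep_findrisc_cutoffs(cohort, 0:26, "diabetes")
  expect_true(all(diff(sweep$sensitivity) <= 1e-12))
  expect_true(all(diff(sweep$specificity) >= -1e-12))
  expect_equal(sweep$sum, sweep$sensitivity + sweep$specificity)
  expect_equal(sweep$roc_distance,
               roc_distance(sweep$sensitivity, sweep$specificity))
})

test_that("the minimum-age filter restricts the analysis set", {
  cohort <- add_glycemic_class(generate_cohort(3000, seed = 13))
  full <- evaluate_model(cohort, findrisc_test(9), "diabetes")
  older <- evaluate_model(cohort, findrisc_test(9), "diabetes", min_age = 45)
  expect_lt(older$n, full$n)
  expect_equal(older$n, sum(cohort$age >= 45))
})

test_that("closed-form generator truth predicts evaluated operating points", {
  cfg <- default_cohort_config()
  cohort <- add_glycemic_class(generate_cohort(20000, cfg, seed = 99))
  for (target in c("diabetes", "prediabetes")) {
    got <- evaluate_model(cohort, hba1c_test(6.5), target)
    want <- oracle_hba1c_operating_point(cfg, 6.5, target)
    n_d <- got$n_disease
    n_n <- got$n - got$n_disease
    se_tol <- 3 * sqrt(want["sensitivity"] * (1 - want["sensitivity"]) / n_d)
    sp_tol <- 3 * sqrt(want["specificity"] * (1 - want["specificity"]) / n_n)
    expect_lt(abs(got$sensitivity / 100 - want["sensitivity"]), se_tol)
    expect_lt(abs(got$specificity / 100 - want["specificity"]), sp_tol)
  }
})
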