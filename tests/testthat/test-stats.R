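test_that("summary-form t test reproduces printed cohort P values", {
  # mean densitometry, carcinoma vs adenoma
  p1 <- t_from_summary(33.4, 4.7, 10, 20.2, 9.2, 9)$p_value
  expect_equal(round(p1, 3), 0.001)
  # axial diameter, carcinoma vs incidentaloma
  p2 <- t_from_summary(62.3, 35.2, 10, 25.9, 1.4, 11)$p_value
  expect_equal(round(p2, 3), 0.003)
  # axial diameter, adenoma vs incidentaloma
  p3 <- t_from_summary(56.6, 42.4, 9, 25.9, 1.4, 11)$p_value
  expect_equal(round(p3, 3), 0.027)
})

test_that("raw and summary t tests agree, and match stats::t.test", {
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1))
    mine <- two_sample_t(x, y)
    via_summary <- t_from_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
    expect_equal(mine, via_summary, tolerance = 1e-12)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    refw <- t.test(x, y)
    w <- two_sample_t(x, y, var_equal = FALSE)
    expect_equal(w$p_value, refw$p.value, tolerance = 1e-10)
    expect_equal(w$df, unname(refw$parameter), tolerance = 1e-10)
  }
  x <- rnorm(5)
  expect_equal(two_sample_t(x, x)$statistic, 0)
  expect_equal(two_sample_t(x, x)$p_value, 1)
  expect_equal(t_from_summary(3, 1, 5, 3, 2, 8)$statistic, 0)
  expect_error(t_from_summary(1, 0, 5, 1, 0, 5), class = "adrenomics_error_degenerate")
  expect_error(two_sample_t(1, c(1, 2)), class = "adrenomics_error_parameter")
})

test_that("Pearson chi-square behaves on canonical 2x2 tables", {
  even <- chi_square_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  diag <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(chi_square_2x2(diag)$statistic, 20)
  expect_lt(chi_square_2x2(diag)$p_value, 0.001)
  set.seed(2)
  tab <- matrix(rpois(4, 8) + 1, 2)
  expect_equal(chi_square_2x2(tab)$statistic, chi_square_2x2(t(tab))$statistic)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               class = "adrenomics_error_degenerate")
})

test_that("feature selection keeps strongly shifted features and nothing at alpha 0", {
  shift <- c(3, rep(0, 31))
  cohort <- generate_cohort(cohort_spec(acc_shift = shift, phases = "unenhanced",
                                        seed = 77))
  sel <- select_features(cohort, alpha = 0.05)
  expect_true("fo_mean" %in% sel$feature)  # the shifted feature is first in the vocabulary
  expect_equal(nrow(select_features(cohort, alpha = 0)), 0)
  expect_error(select_features(dplyr::select(cohort, subject_id, group, phase)),
               class = "adrenomics_error_schema")
})

test_that("ROC with perfect separation reports the midpoint cut-off", {
  r <- roc_youden(c(1, 2, 3, 10, 11, 12),
                  c("benign", "benign", "benign", "malignant", "malignant", "malignant"),
                  positive = "malignant")
  expect_equal(r$auc, 1)
  expect_equal(r$youden_cutoff, 6.5)
  expect_equal(r$youden_sensitivity, 1)
  expect_equal(r$youden_specificity, 1)
  expect_equal(r$orientation, ">")
})

test_that("trapezoid AUC equals the Mann-Whitney oracle and pROC", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    lab <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    sc <- round(rnorm(n), sample(0:1, 1))  # rounding forces ties
    r <- roc_youden(sc, lab)
    oracle <- bf_auc(sc, lab)
    expect_equal(r$auc, max(oracle, 1 - oracle), tolerance = 1e-12)
    pr <- suppressMessages(pROC::roc(lab, sc))
    pa <- as.numeric(pROC::auc(pr))
    expect_equal(r$auc, max(pa, 1 - pa), tolerance = 1e-10)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(15)
  sc <- rnorm(30)
  lab <- runif(30) < 0.4
  r1 <- roc_youden(sc, lab)
  r2 <- roc_youden(exp(sc), lab)
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
  expect_equal(r1$youden_sensitivity, r2$youden_sensitivity)
  expect_equal(r1$youden_specificity, r2$youden_specificity)
})

test_that("the ROC curve is a proper non-decreasing step function", {
  set.seed(16)
  r <- roc_youden(rnorm(40), runif(40) < 0.5)
  curve <- tidy(r)
  o <- order(curve$fpr, curve$sensitivity)
  expect_true(all(diff(curve$sensitivity[o]) >= 0))
  expect_equal(range(curve$fpr), c(0, 1))
  expect_equal(range(curve$sensitivity), c(0, 1))
  expect_gte(r$auc, 0.5)
  expect_error(roc_youden(1:5, rep(TRUE, 5)), class = "adrenomics_error_degenerate")
})

test_that("Youden ties resolve to the lowest threshold", {
  # two thresholds attain J = 0.5; the lower midpoint (1.5) must win
  r <- roc_youden(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(r$youden_cutoff, 1.5)
})
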