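two_blob_matrix <- function(n1 = 15, n2 = 15, gap = 10, p = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n1 * p), n1), matrix(rnorm(n2 * p, mean = gap), n2))
  rownames(x) <- sprintf("S%02d", seq_len(n1 + n2))
  x
}

test_that("standardization gives exact z-scores and is idempotent", {
  x <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- standardize_features(x)$z
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(z), c(a = 0, b = 0), tolerance = 1e-9)
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1), tolerance = 1e-9)
  z2 <- standardize_features(z)$z
  expect_equal(unname(z2), unname(z), tolerance = 1e-9)

  expect_warning(s <- standardize_features(cbind(a = c(1, 2, 3), k = c(5, 5, 5))),
                 "constant")
  expect_equal(s$dropped, "k")
  expect_error(suppressWarnings(standardize_features(cbind(k = c(5, 5, 5)))),
               class = "adrenomics_error_degenerate")
})

test_that("PCA has orthonormal loadings, sorted fractions, full reconstruction", {
  # collinear 2D data: first component carries all the variance
  line <- cbind(1:10, 2 * (1:10)) |> scale()
  p1 <- fit_pca(line)
  expect_equal(p1$variance_fraction[1], 1, tolerance = 1e-9)

  set.seed(3)
  z <- standardize_features(matrix(rnorm(200), 20))$z
  p <- fit_pca(z)
  expect_equal(t(p$loadings) %*% p$loadings, diag(ncol(p$loadings)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  expect_lte(sum(p$variance_fraction), 1 + 1e-9)
  expect_equal(p$scores %*% t(p$loadings), z, tolerance = 1e-8,
               ignore_attr = TRUE)
  # scores of distinct components are uncorrelated
  cc <- crossprod(p$scores[, 1], p$scores[, 2])
  expect_lt(abs(cc), 1e-8)
  expect_error(fit_pca(z, n_components = 50), class = "adrenomics_error_parameter")
})

test_that("isotropic 2D data splits variance evenly between components", {
  set.seed(9)
  z <- standardize_features(matrix(rnorm(8000), 4000))$z
  p <- fit_pca(z)
  expect_equal(p$variance_fraction, c(0.5, 0.5), tolerance = 0.05)
})

test_that("k-means recovers well-separated blobs deterministically", {
  x <- two_blob_matrix()
  z <- standardize_features(x)
  cl <- kmeans_two(z, seed = 0)
  truth <- factor(rep(c("benign", "malignant"), each = 15))
  rates <- detection_rates(cl, truth)
  expect_equal(rates$rate, c(1, 1))
  cl2 <- kmeans_two(z, seed = 0)
  expect_identical(cl$assignment, cl2$assignment)

  # two point-masses: perfect partition with zero within-cluster scatter
  pm <- rbind(matrix(0, 5, 3), matrix(1, 5, 3))
  clp <- kmeans_two(pm, seed = 1)
  expect_equal(clp$wcss, 0)
  expect_equal(length(unique(clp$assignment[1:5])), 1L)
  expect_error(kmeans_two(matrix(0, 1, 3)), class = "adrenomics_error_degenerate")
})

test_that("robust distance rule flags injected far points and only those", {
  set.seed(21)
  blob <- matrix(rnorm(40 * 6), 40)
  rownames(blob) <- sprintf("S%02d", 1:40)
  expect_length(flag_outliers(blob), 0)
  spiked <- blob
  spiked[c(3, 17), ] <- spiked[c(3, 17), ] + 25
  expect_setequal(flag_outliers(spiked), c("S03", "S17"))
  expect_length(flag_outliers(spiked, k_mad = Inf), 0)
  expect_error(flag_outliers(blob[1:3, ]), class = "adrenomics_error_parameter")
})

test_that("group-wise flagging isolates anomalies despite class separation", {
  set.seed(22)
  x <- rbind(matrix(rnorm(10 * 8, mean = 5), 10),  # malignant cluster, far away
             matrix(rnorm(20 * 8), 20))
  rownames(x) <- sprintf("S%02d", 1:30)
  groups <- rep(c("ACC", "benign"), c(10, 20))
  x["S02", ] <- x["S02", ] + 30
  # global rule cannot separate the shifted class from true anomalies...
  expect_gt(length(flag_outliers(x)), 1)
  # ...the group-conditional rule flags exactly the anomaly
  expect_equal(flag_outliers(x, groups = groups), "S02")
})

test_that("detection rates use the majority cluster-class map", {
  truth <- factor(rep(c("malignant", "benign"), c(8, 20)))
  perfect <- rep(c(1L, 2L), c(8, 20))
  r <- detection_rates(perfect, truth)
  expect_equal(r$rate[r$class == "malignant"], 1)
  expect_equal(r$rate[r$class == "benign"], 1)

  # one error on each side: the 7/8 and 19/20 configuration
  nearly <- perfect
  nearly[1] <- 2L
  nearly[9] <- 1L
  r2 <- detection_rates(nearly, truth)
  expect_equal(r2$n_correct[r2$class == "malignant"], 7L)
  expect_equal(r2$rate[r2$class == "malignant"], 7 / 8)
  expect_equal(r2$n_correct[r2$class == "benign"], 19L)
  expect_equal(r2$rate[r2$class == "benign"], 19 / 20)

  # swapping cluster ids changes nothing
  r3 <- detection_rates(3L - nearly, truth)
  expect_equal(r2$rate, r3$rate)
})

test_that("run_unsupervised recovers classes and excludes injected outliers", {
  cohort <- generate_cohort(cohort_spec(separation = 5, n_outliers = 2,
                                        phases = "unenhanced", seed = 12))
  res <- run_unsupervised(cohort, phase = "unenhanced")
  injected <- unique(cohort$subject_id[cohort$injected_outlier])
  expect_setequal(res$outliers, injected)
  expect_false(any(res$subjects$subject_id %in% injected))
  expect_equal(res$rates$rate, c(1, 1))
  g <- glance(res)
  expect_equal(g$n_outliers, 2L)
  expect_equal(g$rate_malignant, 1)
  expect_true(all(diff(res$pca$variance_fraction) <= 1e-12))
})

test_that("with no class structure, detection hovers near chance", {
  rates <- vapply(1:8, function(s) {
    cohort <- generate_cohort(cohort_spec(n_acc = 70, n_adenoma = 60, n_ai = 70,
                                          separation = 0, phases = "unenhanced",
                                          seed = s))
    res <- run_unsupervised(cohort, phase = "unenhanced", k_mad = Inf)
    mean(res$rates$rate)
  }, numeric(1))
  # optimal mapping of arbitrary clusters to labels sits just above 1/2
  expect_lt(mean(rates), 0.65)
  expect_gt(mean(rates), 0.45)
})
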