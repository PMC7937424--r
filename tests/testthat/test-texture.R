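sample_from <- function(values) {
  structure(list(values = as.numeric(values),
                 coords = cbind(seq_along(values), 1L, 1L),
                 voxel_count = length(values),
                 grid_dim = c(length(values), 1L, 1L),
                 spacing = c(1, 1, 1)),
            class = "voi_sample")
}

test_that("quantization maps min-max uniformly onto 1..Ng", {
  expect_equal(quantize_voi(sample_from(c(0, 10)), 2)$levels, c(1L, 2L))
  expect_equal(quantize_voi(sample_from(rep(7, 5)), 8)$levels, rep(1L, 5))
  expect_equal(quantize_voi(sample_from(0:31), 32)$levels, 1:32)
  expect_error(quantize_voi(sample_from(1:4), 1), class = "adrenomics_error_parameter")
})

test_that("first-order features match their definitions", {
  f <- first_order_features(c(10, 20, 30))
  expect_equal(f[["fo_mean"]], 20)
  expect_equal(f[["fo_sd"]], 10)
  expect_equal(f[["fo_skewness"]], 0)

  const <- first_order_features(rep(4, 10))
  expect_equal(const[["fo_sd"]], 0)
  expect_equal(const[["fo_entropy"]], 0)
  expect_equal(const[["fo_skewness"]], 0)

  # 32 values filling 32 bins equally -> entropy log2(32) = 5 bits
  expect_equal(first_order_features(0:31, n_grey = 32)[["fo_entropy"]], 5)

  # kurtosis convention: raw m4/m2^2 (a symmetric two-point sample gives 1)
  expect_equal(first_order_features(c(-1, 1, -1, 1))[["fo_kurtosis"]], 1)
})

test_that("GLCM of the two-row toy grid matches hand enumeration", {
  # 2x2x1 grid, levels [[1,1],[2,2]] (rows i, columns j), pairs along j only
  q <- voi_as_quantized(list(dims = c(2L, 2L, 1L),
                             coords = cbind(c(1L, 2L, 1L, 2L), c(1L, 1L, 2L, 2L), 1L),
                             levels = c(1L, 2L, 1L, 2L), ng = 2L))
  g <- compute_glcm(q, offsets = matrix(c(0L, 1L, 0L), 1))
  expect_equal(g$n_pairs, 4)
  expect_equal(g$p, matrix(c(0.5, 0, 0, 0.5), 2))
  f <- glcm_features(g)
  expect_equal(f[["glcm_entropy"]], 1)
  expect_equal(f[["glcm_autocorrelation"]], 2.5)
  expect_equal(f[["glcm_homogeneity_idm"]], 1)
  expect_equal(f[["glcm_maximum_probability"]], 0.5)
})

test_that("constant VOI gives a point-mass co-occurrence matrix", {
  vol <- ct_volume(array(12, c(3, 3, 1)), c(1, 1, 1))
  mask <- voi_mask(array(TRUE, c(3, 3, 1)), c(1, 1, 1))
  q <- quantize_voi(extract_voi(vol, mask), 8)
  g <- compute_glcm(q)
  expect_equal(g$p[1, 1], 1)
  expect_equal(sum(g$p), 1)
  f <- glcm_features(g)
  expect_equal(f[["glcm_entropy"]], 0)
  expect_equal(f[["glcm_maximum_probability"]], 1)
  expect_equal(f[["glcm_homogeneity_idm"]], 1)
  expect_equal(f[["glcm_energy"]], 1)
  expect_equal(f[["glcm_contrast"]], 0)
})

test_that("GLCM is symmetric, normalized, and defined only with pairs", {
  for (s in 1:10) {
    v <- random_small_voi(s)
    g <- compute_glcm(voi_as_quantized(v))
    expect_equal(sum(g$p), 1, tolerance = 1e-9)
    expect_equal(g$p, t(g$p), tolerance = 1e-12)
    expect_equal(sum(g$p_sum), 1, tolerance = 1e-9)
    expect_equal(sum(g$p_diff), 1, tolerance = 1e-9)
  }
  # single-voxel VOI: no pairs
  q1 <- voi_as_quantized(list(dims = c(3L, 3L, 1L), coords = cbind(2L, 2L, 1L),
                              levels = 1L, ng = 4L))
  expect_error(compute_glcm(q1), class = "adrenomics_error_degenerate")
})

test_that("run decomposition matches hand enumeration", {
  row_voi <- function(levels) {
    voi_as_quantized(list(dims = c(length(levels), 1L, 1L),
                          coords = cbind(seq_along(levels), 1L, 1L),
                          levels = as.integer(levels), ng = max(levels)))
  }
  horiz <- matrix(c(1L, 0L, 0L), 1)

  r <- compute_rlm(row_voi(c(1, 1, 2, 2, 2)), offsets = horiz)
  expect_equal(r$n_runs, 2)
  expect_equal(r$n_voxels_traversed, 5)
  expect_equal(r$r[1, 2], 1)
  expect_equal(r$r[2, 3], 1)
  expect_equal(sum(r$r), 2)
  f <- rlm_features(r)
  expect_equal(f[["rlm_sre"]], (1 / 4 + 1 / 9) / 2)
  expect_equal(f[["rlm_lre"]], 6.5)
  expect_equal(f[["rlm_rp"]], 0.4)
  expect_equal(f[["rlm_gln"]], 1)
  expect_equal(f[["rlm_lgre"]], 0.625)
  expect_equal(f[["rlm_hgre"]], 2.5)

  # alternating levels: only unit runs
  ra <- compute_rlm(row_voi(c(1, 2, 1, 2)), offsets = horiz)
  expect_equal(ra$n_runs, 4)
  expect_true(all(ra$r[, -1] == 0))

  # constant row of n voxels: a single run of length n
  n <- 7
  rc <- compute_rlm(row_voi(rep(1, n)), offsets = horiz)
  expect_equal(rc$n_runs, 1)
  fc <- rlm_features(rc)
  expect_equal(fc[["rlm_sre"]], 1 / n^2)
  expect_equal(fc[["rlm_lre"]], n^2)
  expect_equal(fc[["rlm_rp"]], 1 / n)
})

test_that("run-length accounting holds per direction on random VOIs", {
  offs <- direction_offsets("3d")
  for (s in 11:20) {
    v <- random_small_voi(s)
    q <- voi_as_quantized(v)
    # pooled over all directions: sum_j j * r(i,j) = n_dirs * n_voxels
    r <- compute_rlm(q)
    expect_equal(sum(sweep(r$r, 2, seq_len(ncol(r$r)), `*`)),
                 nrow(offs) * length(v$levels))
    # and per single direction
    r1 <- compute_rlm(q, offsets = offs[sample(nrow(offs), 1), , drop = FALSE])
    expect_equal(sum(sweep(r1$r, 2, seq_len(ncol(r1$r)), `*`)), length(v$levels))
  }
})

test_that("GLCM and RLM features agree with brute-force oracles", {
  offs <- direction_offsets("3d")
  for (s in 30:35) {
    v <- random_small_voi(s)
    q <- voi_as_quantized(v)
    g <- compute_glcm(q)
    bg <- bf_glcm(v, offs)
    expect_equal(g$p, bg$p, tolerance = 1e-12)
    expect_equal(glcm_features(g), bf_glcm_features(bg$p), tolerance = 1e-9)
    r <- compute_rlm(q)
    br <- bf_rlm(v, offs, lmax = max(v$dims))
    expect_equal(unname(r$r), unname(br$r))
    expect_equal(rlm_features(r), bf_rlm_features(br$r, br$n_runs, br$np),
                 tolerance = 1e-9)
  }
})

test_that("extract_features returns exactly the 32 named features", {
  ph <- generate_phantom(phantom_spec("adenoma", seed = 2))
  f <- extract_features(ph$volumes$unenhanced, ph$mask)
  expect_equal(intersect(names(f), radiomic_feature_names()),
               radiomic_feature_names())
  expect_equal(length(radiomic_feature_names()), 32L)
  expect_true(all(is.finite(unlist(f[radiomic_feature_names()]))))
  # determinism
  f2 <- extract_features(ph$volumes$unenhanced, ph$mask)
  expect_identical(f, f2)
})

test_that("constant HU offsets change only the first-order mean", {
  ph <- generate_phantom(phantom_spec("carcinoma", seed = 31))
  vol <- ph$volumes$unenhanced
  shifted <- ct_volume(vol$values + 100, vol$spacing, vol$phase)
  f0 <- extract_features(vol, ph$mask)
  f1 <- extract_features(shifted, ph$mask)
  expect_equal(f1$fo_mean, f0$fo_mean + 100)
  other <- setdiff(radiomic_feature_names(), "fo_mean")
  expect_equal(as.numeric(f1[other]), as.numeric(f0[other]), tolerance = 1e-9)
})

test_that("constant phantoms give the degenerate feature values", {
  vol <- ct_volume(array(50, c(4, 4, 2)), c(1, 1, 1))
  mask <- voi_mask(array(TRUE, c(4, 4, 2)), c(1, 1, 1))
  f <- extract_features(vol, mask)
  expect_equal(f$fo_entropy, 0)
  expect_equal(f$glcm_entropy, 0)
  expect_equal(f$glcm_homogeneity_idm, 1)
  expect_equal(f$glcm_energy, 1)
})
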