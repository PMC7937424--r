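# First-order features and assembly of the full 32-feature vector.

#' First-order (histogram) features of a VOI
#'
#' Five intensity-histogram statistics of the raw HU values: mean, sample
#' standard deviation, skewness and kurtosis as the standardized third and
#' fourth central moments (kurtosis is the raw `m4 / m2^2`, i.e. 3 for a
#' normal sample in the large-n limit, with no excess correction), and the
#' base-2 entropy of the `n_grey`-bin min-max histogram. Skewness and
#' kurtosis are defined as 0 for a constant VOI.
#'
#' @param sample A `voi_sample` from [extract_voi()] or a numeric vector of
#'   HU values.
#' @param n_grey Number of histogram bins for the entropy (default 32,
#'   matching the grey-level quantization of the second-order features).
#' @return Named numeric vector `fo_mean`, `fo_sd`, `fo_skewness`,
#'   `fo_kurtosis`, `fo_entropy`.
#' @export
first_order_features <- function(sample, n_grey = 32L) {
  v <- if (inherits(sample, "voi_sample")) sample$values else as.numeric(sample)
  if (length(v) == 0L) abort_empty_voi("cannot compute features of an empty VOI")
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)

  n_grey <- as.integer(n_grey)
  if (is.na(n_grey) || n_grey < 2L) abort_parameter("`n_grey` must be an integer >= 2")
  lo <- min(v)
  hi <- max(v)
  if (hi > lo) {
    lvl <- pmin(floor((v - lo) / (hi - lo) * n_grey) + 1L, n_grey)
    q <- tabulate(lvl, n_grey) / length(v)
  } else {
    q <- c(1, rep(0, n_grey - 1L))
  }

  c(
    fo_mean = mu,
    fo_sd = if (length(v) > 1L) stats::sd(v) else 0,
    fo_skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    fo_kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    fo_entropy = entropy_bits(q)
  )
}

#' Names of the 32 radiomic features
#'
#' The fixed feature vocabulary of the signature: 5 first-order, 16 GLCM
#' (Haralick) and 11 RLM (Galloway) features, in the column order produced
#' by [extract_features()].
#'
#' @return Character vector of length 32.
#' @export
radiomic_feature_names <- function() {
  c("fo_mean", "fo_sd", "fo_skewness", "fo_kurtosis", "fo_entropy",
    "glcm_autocorrelation", "glcm_cluster_prominence", "glcm_cluster_shade",
    "glcm_contrast", "glcm_correlation", "glcm_difference_entropy",
    "glcm_difference_variance", "glcm_dissimilarity", "glcm_energy",
    "glcm_entropy", "glcm_homogeneity_idm", "glcm_maximum_probability",
    "glcm_sum_average", "glcm_sum_entropy", "glcm_sum_variance",
    "glcm_variance",
    "rlm_sre", "rlm_lre", "rlm_gln", "rlm_rln", "rlm_rp", "rlm_lgre",
    "rlm_hgre", "rlm_srlge", "rlm_srhge", "rlm_lrlge", "rlm_lrhge")
}

#' Extract the 32-feature radiomic vector of a lesion
#'
#' Composes VOI extraction, grey-level quantization, and the first-order,
#' GLCM and RLM feature computations into one tidy row per (lesion, phase).
#'
#' @param volume A [ct_volume()].
#' @param mask The paired [voi_mask()].
#' @param n_grey Grey levels for quantization and histogram entropy
#'   (default 32).
#' @param mode Direction handling for the second-order features, `"3d"`
#'   (13 pooled directions) or `"2d"` (4 in-plane directions).
#' @param distance Co-occurrence offset length in voxels.
#'
#' @return A one-row tibble: `subject_id`, `phase`, `voxel_count`, the 32
#'   feature columns named as in [radiomic_feature_names()], and the
#'   provenance columns `n_grey`, `direction_mode`, `distance`.
#' @export
extract_features <- function(volume, mask, n_grey = 32L, mode = c("3d", "2d"),
                             distance = 1L) {
  mode <- match.arg(mode)
  sample <- extract_voi(volume, mask)
  fo <- first_order_features(sample, n_grey = n_grey)
  q <- quantize_voi(sample, n_grey = n_grey)
  gl <- glcm_features(compute_glcm(q, mode = mode, distance = distance))
  rl <- rlm_features(compute_rlm(q, mode = mode))
  feats <- c(fo, gl, rl)
  stopifnot(identical(names(feats), radiomic_feature_names()))
  dplyr::bind_cols(
    tibble(subject_id = volume$subject_id, phase = volume$phase,
           voxel_count = sample$voxel_count),
    as_tibble(as.list(feats)),
    tibble(n_grey = as.integer(n_grey), direction_mode = mode,
           distance = as.integer(distance))
  )
}
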