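# Unsupervised arm: standardization, PCA for visualization, k-means with
# k = 2, robust outlier flagging, and per-class detection rates.

as_feature_matrix <- function(x) {
  if (inherits(x, "standardized_features")) return(x$z)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' Column-wise standardization of a feature matrix
#'
#' Centres each feature to mean 0 and scales to unit sample SD. Constant
#' features carry no clustering information and break the scaling, so they
#' are dropped with a warning.
#'
#' @param x Numeric matrix or data frame (subjects x features). Row names
#'   are kept as subject identifiers.
#' @return An object of class `standardized_features`: `z` (the z-score
#'   matrix), `center`, `scale`, `dropped` (names of removed columns).
#' @export
standardize_features <- function(x) {
  x <- as_feature_matrix(x)
  if (nrow(x) < 2L) abort_parameter("need at least two subjects to standardize")
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 1e-12
  if (!any(keep)) abort_degenerate("all feature columns are constant")
  dropped <- colnames(x)[!keep]
  if (length(dropped) > 0) {
    warn(paste0("dropping constant features: ", paste(dropped, collapse = ", ")))
  }
  x <- x[, keep, drop = FALSE]
  ctr <- colMeans(x)
  z <- scale(x, center = ctr, scale = sds[keep])
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  structure(list(z = z, center = ctr, scale = sds[keep], dropped = dropped),
            class = "standardized_features")
}

#' Principal component analysis of standardized features
#'
#' Thin wrapper over the singular value decomposition with a deterministic
#' sign convention (the largest-magnitude loading of each component is made
#' positive). Input is assumed already centred/standardized; variance
#' fractions are relative to the total variance of all components.
#'
#' @param x A [standardize_features()] result or numeric matrix.
#' @param n_components Components to retain (default: all).
#' @return An object of class `pca_result`: `loadings` (features x k,
#'   orthonormal), `scores` (subjects x k), `variance_fraction` (length k,
#'   non-increasing), `total_components`.
#' @export
fit_pca <- function(x, n_components = NULL) {
  z <- as_feature_matrix(x)
  k_max <- min(dim(z))
  n_components <- n_components %||% k_max
  if (n_components < 1 || n_components > k_max) {
    abort_parameter(paste0("`n_components` must lie in 1..", k_max))
  }
  pr <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  load <- pr$rotation
  scores <- pr$x
  for (c_i in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, c_i])), c_i] < 0) {
      load[, c_i] <- -load[, c_i]
      scores[, c_i] <- -scores[, c_i]
    }
  }
  keep <- seq_len(n_components)
  structure(
    list(loadings = load[, keep, drop = FALSE],
         scores = scores[, keep, drop = FALSE],
         variance_fraction = vf[keep],
         total_components = length(vf)),
    class = "pca_result"
  )
}

#' @describeIn fit_pca Per-subject component scores as a tibble.
#' @param x A `pca_result`.
#' @param ... Unused.
#' @export
tidy.pca_result <- function(x, ...) {
  scores <- as_tibble(x$scores, .name_repair = "minimal")
  names(scores) <- paste0("PC", seq_len(ncol(scores)))
  dplyr::bind_cols(tibble(subject_id = rownames(x$scores) %||%
                            as.character(seq_len(nrow(x$scores)))), scores)
}

#' @describeIn fit_pca Variance fractions per retained component.
#' @export
glance.pca_result <- function(x, ...) {
  tibble(component = seq_along(x$variance_fraction),
         variance_fraction = x$variance_fraction)
}

#' Two-cluster k-means
#'
#' Lloyd's algorithm with `k = 2`, run from `restarts` random
#' initializations; the partition with the smallest within-cluster sum of
#' squares wins. The seed makes the whole procedure reproducible.
#'
#' @param x A [standardize_features()] result or numeric matrix
#'   (subjects x features).
#' @param seed Integer RNG seed (default 0).
#' @param restarts Random restarts (default 50).
#' @return An object of class `cluster_result`: `assignment` (named integer
#'   vector in {1, 2}), `centers`, `wcss`, `seed`, `restarts`.
#' @export
kmeans_two <- function(x, seed = 0L, restarts = 50L) {
  z <- as_feature_matrix(x)
  if (nrow(z) < 2L) abort_degenerate("need at least two subjects for two clusters")
  withr::local_seed(seed)
  km <- suppressWarnings(
    stats::kmeans(z, centers = 2L, nstart = restarts, iter.max = 300L,
                  algorithm = "Lloyd")
  )
  assignment <- setNames(as.integer(km$cluster),
                         rownames(z) %||% as.character(seq_len(nrow(z))))
  structure(
    list(assignment = assignment, centers = km$centers,
         wcss = km$tot.withinss, seed = as.integer(seed),
         restarts = as.integer(restarts)),
    class = "cluster_result"
  )
}

#' Flag gross outliers by robust distance
#'
#' Computes each subject's Euclidean distance from the coordinate-wise
#' median and flags those exceeding `median(d) + k_mad * mad(d)` (MAD with
#' the usual 1.4826 normal-consistency constant), in a single pass. With
#' `groups` supplied, each subject's distance is measured from its own
#' group's coordinate-wise median — the appropriate reading when classes
#' are well separated and an anomaly (for instance a massively calcified
#' carcinoma) is extreme relative to its peers — while the flagging
#' threshold is still estimated from the pooled distances of all subjects,
#' because median/MAD estimates from ten-subject groups are too unstable to
#' threshold on.
#'
#' @param x A [standardize_features()] result or numeric matrix with row
#'   names as subject ids.
#' @param k_mad MAD multiplier (default 3). `Inf` flags nothing.
#' @param groups Optional per-subject grouping vector for within-group
#'   flagging. Default `NULL`: one global pass.
#' @return Character vector of flagged subject ids (integer indices when
#'   the matrix has no row names).
#' @export
flag_outliers <- function(x, k_mad = 3, groups = NULL) {
  z <- as_feature_matrix(x)
  if (nrow(z) < 4L) abort_parameter("need at least four subjects to flag outliers")
  ids <- rownames(z) %||% seq_len(nrow(z))
  dist_from <- function(idx) {
    zz <- z[idx, , drop = FALSE]
    med <- apply(zz, 2, stats::median)
    sqrt(rowSums(sweep(zz, 2, med)^2))
  }
  d <- numeric(nrow(z))
  if (is.null(groups)) {
    d <- dist_from(seq_len(nrow(z)))
  } else {
    if (length(groups) != nrow(z)) abort_parameter("`groups` must match the number of rows")
    for (idx in split(seq_len(nrow(z)), groups)) d[idx] <- dist_from(idx)
  }
  ids[d > stats::median(d) + k_mad * stats::mad(d)]
}

#' Per-class detection rates of a 2-cluster partition
#'
#' Maps the two clusters to the two true classes by majority (the bijection
#' maximizing total agreement, ties broken towards the first) and reports,
#' for each class, the fraction of its members falling in the cluster
#' mapped to it.
#'
#' @param assignment Cluster labels in {1, 2} per subject (e.g. from
#'   [kmeans_two()]), or a `cluster_result`.
#' @param labels True class per subject; must have exactly two distinct
#'   values among the retained subjects.
#' @return Tibble with one row per class: `class`, `n`, `n_correct`,
#'   `rate`; the chosen cluster-to-class map is in attribute `mapping`.
#' @export
detection_rates <- function(assignment, labels) {
  if (inherits(assignment, "cluster_result")) assignment <- assignment$assignment
  labels <- as.factor(as.character(labels))
  if (length(labels) != length(assignment)) {
    abort_parameter("`labels` must match `assignment` in length")
  }
  if (nlevels(labels) != 2L) {
    abort_degenerate("detection rates need exactly two classes among retained subjects")
  }
  tab <- table(labels, factor(assignment, levels = c(1L, 2L)))
  straight <- tab[1, 1] + tab[2, 2]
  crossed <- tab[1, 2] + tab[2, 1]
  if (straight >= crossed) {
    mapping <- setNames(levels(labels), c("1", "2"))
    correct <- c(tab[1, 1], tab[2, 2])
  } else {
    mapping <- setNames(rev(levels(labels)), c("1", "2"))
    correct <- c(tab[1, 2], tab[2, 1])
  }
  out <- tibble(class = levels(labels),
                n = as.integer(rowSums(tab)),
                n_correct = as.integer(correct),
                rate = as.numeric(correct / rowSums(tab)))
  attr(out, "mapping") <- mapping
  out
}

#' Run the full unsupervised analysis of one phase
#'
#' Standardizes the feature matrix, flags and removes gross outliers
#' (within-group robust distances by default), re-standardizes the retained
#' subjects, clusters them with two-cluster k-means on the full feature
#' space, computes a PCA of the same matrix for 2D visualization, and
#' scores the clustering against the supplied group labels as per-class
#' (malignant/benign) detection rates.
#'
#' @param data Cohort tibble with `subject_id`, `group`, `phase` and
#'   feature columns.
#' @param phase Phase to analyse; may be omitted when `data` holds a single
#'   phase.
#' @param features Feature columns; defaults to the radiomic names present.
#' @param malignant_groups Group levels counted as malignant (default
#'   `"ACC"`).
#' @param k_mad MAD multiplier for outlier flagging; `Inf` disables removal.
#' @param outliers_by_group Flag outliers within each group (default) or
#'   globally.
#' @param seed,restarts k-means reproducibility settings.
#' @param n_components PCA components kept for visualization (default 2).
#' @return An object of class `unsupervised_result`: `rates`,
#'   `cluster` (a `cluster_result`), `pca` (a `pca_result`), `outliers`,
#'   `subjects` (per-subject tibble), `phase`, `mapping`.
#' @export
run_unsupervised <- function(data, phase = NULL, features = NULL,
                             malignant_groups = "ACC", k_mad = 3,
                             outliers_by_group = TRUE,
                             seed = 0L, restarts = 50L, n_components = 2L) {
  if (!all(c("subject_id", "group", "phase") %in% names(data))) {
    abort_schema("`data` must have subject_id, group and phase columns")
  }
  phases_present <- unique(data$phase)
  if (is.null(phase)) {
    if (length(phases_present) > 1L) {
      abort_parameter("`data` holds several phases; pick one with `phase`")
    }
    phase <- phases_present
  }
  d <- data[data$phase == phase, , drop = FALSE]
  if (nrow(d) < 4L) abort_degenerate("need at least four subjects in the phase")
  features <- features %||% intersect(radiomic_feature_names(), names(d))
  if (length(features) == 0) abort_schema("no feature columns found")

  x <- as.matrix(d[, features, drop = FALSE])
  rownames(x) <- d$subject_id
  std_all <- suppressWarnings(standardize_features(x))
  class_of <- function(g) ifelse(as.character(g) %in% malignant_groups,
                                 "malignant", "benign")
  outliers <- if (is.finite(k_mad)) {
    flag_outliers(std_all, k_mad = k_mad,
                  groups = if (outliers_by_group) class_of(d$group))
  } else character()

  retained <- !(d$subject_id %in% outliers)
  if (sum(retained) < 4L) abort_degenerate("too few subjects left after outlier removal")
  std <- suppressWarnings(standardize_features(x[retained, , drop = FALSE]))
  cl <- kmeans_two(std, seed = seed, restarts = restarts)
  pca <- fit_pca(std, n_components = min(n_components, min(dim(std$z))))

  truth <- factor(ifelse(as.character(d$group[retained]) %in% malignant_groups,
                         "malignant", "benign"),
                  levels = c("benign", "malignant"))
  rates <- detection_rates(cl$assignment, truth)
  mapping <- attr(rates, "mapping")

  subjects <- tibble(
    subject_id = d$subject_id[retained],
    group = d$group[retained],
    truth = truth,
    cluster = unname(cl$assignment),
    predicted = unname(mapping[as.character(cl$assignment)]),
    pc1 = unname(pca$scores[, 1]),
    pc2 = if (ncol(pca$scores) > 1) unname(pca$scores[, 2]) else NA_real_
  )

  structure(
    list(rates = rates, cluster = cl, pca = pca, outliers = outliers,
         subjects = subjects, phase = phase, mapping = mapping,
         dropped_features = std$dropped),
    class = "unsupervised_result"
  )
}

#' @export
print.unsupervised_result <- function(x, ...) {
  cat(sprintf("<unsupervised_result> phase %s: %d subjects, %d outlier(s) removed\n",
              x$phase, nrow(x$subjects), length(x$outliers)))
  print(x$rates)
  invisible(x)
}

#' @describeIn run_unsupervised Per-subject assignments and PC scores.
#' @param x An `unsupervised_result`.
#' @param ... Unused.
#' @export
tidy.unsupervised_result <- function(x, ...) x$subjects

#' @describeIn run_unsupervised One-row summary of rates, variance
#'   fractions and outlier count.
#' @export
glance.unsupervised_result <- function(x, ...) {
  r <- setNames(x$rates$rate, x$rates$class)
  tibble(
    phase = x$phase,
    n_subjects = nrow(x$subjects),
    n_outliers = length(x$outliers),
    rate_malignant = unname(r["malignant"]),
    rate_benign = unname(r["benign"]),
    pc1_variance = x$pca$variance_fraction[1],
    pc2_variance = if (length(x$pca$variance_fraction) > 1)
      x$pca$variance_fraction[2] else NA_real_,
    wcss = x$cluster$wcss
  )
}

#' @describeIn run_unsupervised Cluster scatter on the first two principal
#'   components, colour-coded by cluster, shaped by true group, with
#'   cluster centres as large markers.
#' @param object An `unsupervised_result`.
#' @export
autoplot.unsupervised_result <- function(object, ...) {
  d <- object$subjects
  centres <- dplyr::summarise(d, pc1 = mean(.data$pc1), pc2 = mean(.data$pc2),
                              .by = "cluster")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$cluster),
                                     shape = .data$group), size = 2) +
    ggplot2::geom_point(data = centres,
                        ggplot2::aes(colour = factor(.data$cluster)),
                        size = 5, alpha = 0.5) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$pca$variance_fraction[1]),
      y = if (length(object$pca$variance_fraction) > 1)
        sprintf("PC2 (%.1f%%)", 100 * object$pca$variance_fraction[2]) else "PC2",
      colour = "Cluster", shape = "Group",
      title = sprintf("K-means clustering, %s phase", object$phase)
    ) +
    ggplot2::theme_minimal()
}
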