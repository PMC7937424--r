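# Grey-level co-occurrence matrix (GLCM) and the Haralick feature set.

#' Direction offsets for co-occurrence and run-length analysis
#'
#' `"3d"` gives the 13 unique nearest-neighbour directions of a 3D lattice
#' (each direction and its negation are pooled by symmetrization);
#' `"2d"` gives the 4 in-plane directions applied slice-wise.
#'
#' @param mode `"3d"` or `"2d"`.
#' @return Integer matrix with one `(di, dj, dk)` offset per row. The first
#'   non-zero component of every offset is positive.
#' @export
direction_offsets <- function(mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  offs <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, -1, 0),
    c(0, 0, 1),
    c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, -1, 1), c(1, 1, -1), c(1, -1, -1)
  )
  storage.mode(offs) <- "integer"
  if (mode == "2d") offs[1:4, , drop = FALSE] else offs
}

#' Compute the grey-level co-occurrence matrix of a VOI
#'
#' For every direction offset, ordered pairs of in-VOI voxels separated by
#' the offset are counted; pairs involving a voxel outside the VOI are
#' skipped. Counts are symmetrized (each unordered pair contributes in both
#' orders), pooled across all directions into a single matrix, and
#' normalized to probabilities.
#'
#' @param q A [quantize_voi()] result.
#' @param mode Direction set, `"3d"` (13 directions, default) or `"2d"`
#'   (4 in-plane directions per slice).
#' @param distance Offset length in voxels (default 1).
#' @param offsets Optional integer matrix of direction offsets overriding
#'   `mode`, one `(di, dj, dk)` row per direction.
#'
#' @return An object of class `glcm`: `p` (Ng x Ng probability matrix,
#'   symmetric, summing to 1), marginals `p_x`/`p_y`, diagonal sums
#'   `p_sum` (indexed k = 2..2Ng) and `p_diff` (k = 0..Ng-1), `n_pairs`,
#'   `n_grey`, `mode`, `distance`.
#' @export
compute_glcm <- function(q, mode = c("3d", "2d"), distance = 1L, offsets = NULL) {
  stopifnot(inherits(q, "quantized_voi"))
  mode <- match.arg(mode)
  if (is.null(offsets)) offsets <- direction_offsets(mode)
  distance <- as.integer(distance)
  if (is.na(distance) || distance < 1L) abort_parameter("`distance` must be a positive integer")
  offsets <- offsets * distance

  ng <- q$n_grey
  dims <- q$grid_dim
  L <- array(0L, dims)
  L[q$coords] <- q$levels

  counts <- numeric(ng * ng)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    lo <- pmax(1L, 1L - o)
    hi <- pmin(dims, dims - o)
    if (any(lo > hi)) next
    si <- seq.int(lo[1], hi[1])
    sj <- seq.int(lo[2], hi[2])
    sk <- seq.int(lo[3], hi[3])
    a <- L[si, sj, sk, drop = FALSE]
    b <- L[si + o[1], sj + o[2], sk + o[3], drop = FALSE]
    keep <- a > 0L & b > 0L
    if (!any(keep)) next
    av <- a[keep]
    bv <- b[keep]
    counts <- counts + tabulate(av + (bv - 1L) * ng, ng * ng) +
      tabulate(bv + (av - 1L) * ng, ng * ng)
  }
  n_pairs <- sum(counts)
  if (n_pairs == 0) {
    abort_degenerate("no co-occurring voxel pairs in the VOI (too small or too scattered)")
  }
  p <- matrix(counts / n_pairs, ng, ng)

  k_sum <- as.vector(row(p) + col(p))
  k_diff <- as.vector(abs(row(p) - col(p)))
  p_sum <- vapply(2:(2 * ng), function(k) sum(p[k_sum == k]), numeric(1))
  p_diff <- vapply(0:(ng - 1), function(k) sum(p[k_diff == k]), numeric(1))

  structure(
    list(p = p, p_x = rowSums(p), p_y = colSums(p),
         p_sum = p_sum, p_diff = p_diff,
         n_pairs = n_pairs, n_grey = ng, mode = mode, distance = distance),
    class = "glcm"
  )
}

#' Haralick features of a co-occurrence matrix
#'
#' The 16 GLCM features of the radiomic signature. Logarithms are base 2
#' with `0 log 0 := 0`; correlation is defined as 0 when either marginal
#' variance vanishes.
#'
#' @param m A [compute_glcm()] result.
#' @return Named numeric vector of 16 features, names prefixed `glcm_`.
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "glcm"))
  p <- m$p
  ng <- m$n_grey
  i <- row(p)
  j <- col(p)
  lev <- seq_len(ng)

  mu_x <- sum(lev * m$p_x)
  mu_y <- sum(lev * m$p_y)
  sig_x <- sqrt(sum((lev - mu_x)^2 * m$p_x))
  sig_y <- sqrt(sum((lev - mu_y)^2 * m$p_y))

  autocorrelation <- sum(i * j * p)
  correlation <- if (sig_x * sig_y > 0) (autocorrelation - mu_x * mu_y) / (sig_x * sig_y) else 0

  ks <- 2:(2 * ng)
  kd <- 0:(ng - 1)
  sum_average <- sum(ks * m$p_sum)
  mu_diff <- sum(kd * m$p_diff)

  c(
    glcm_autocorrelation = autocorrelation,
    glcm_cluster_prominence = sum((i + j - mu_x - mu_y)^4 * p),
    glcm_cluster_shade = sum((i + j - mu_x - mu_y)^3 * p),
    glcm_contrast = sum((i - j)^2 * p),
    glcm_correlation = correlation,
    glcm_difference_entropy = entropy_bits(m$p_diff),
    glcm_difference_variance = sum((kd - mu_diff)^2 * m$p_diff),
    glcm_dissimilarity = sum(abs(i - j) * p),
    glcm_energy = sum(p^2),
    glcm_entropy = entropy_bits(p),
    glcm_homogeneity_idm = sum(p / (1 + (i - j)^2)),
    glcm_maximum_probability = max(p),
    glcm_sum_average = sum_average,
    glcm_sum_entropy = entropy_bits(m$p_sum),
    glcm_sum_variance = sum((ks - sum_average)^2 * m$p_sum),
    glcm_variance = sum((i - (mu_x + mu_y) / 2)^2 * p)
  )
}
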