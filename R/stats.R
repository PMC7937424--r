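# Univariate group comparisons and feature selection.

# vectorized two-sample t machinery; returns NA rows where the standard
# error vanishes instead of failing, so callers can decide
t_stats_ <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y, var_equal = TRUE) {
  if (var_equal) {
    df <- n_x + n_y - 2
    sp2 <- ((n_x - 1) * sd_x^2 + (n_y - 1) * sd_y^2) / df
    se <- sqrt(sp2 * (1 / n_x + 1 / n_y))
  } else {
    vx <- sd_x^2 / n_x
    vy <- sd_y^2 / n_y
    se <- sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (n_x - 1) + vy^2 / (n_y - 1))
  }
  est <- mean_x - mean_y
  t <- ifelse(se > 0, est / se, NA_real_)
  tibble(estimate = est, statistic = t, df = ifelse(se > 0, df, NA_real_),
         p_value = 2 * pt(-abs(t), df))
}

#' Two-sample t test from summary statistics
#'
#' Computes Student's two-sample t test directly from the printed
#' `mean (s.d.) / n` summaries of two groups — algebraically identical to
#' running the raw-sample test on any data having those summaries. The
#' default is the pooled-variance (equal-variance) form; `var_equal = FALSE`
#' gives Welch's test with Satterthwaite degrees of freedom.
#'
#' @param mean_x,sd_x,n_x Mean, SD and size of the first group.
#' @param mean_y,sd_y,n_y Mean, SD and size of the second group.
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @return A one-row tibble: `estimate` (mean difference), `statistic`,
#'   `df`, `p_value` (two-sided).
#' @export
t_from_summary <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y, var_equal = TRUE) {
  if (any(c(n_x, n_y) < 2)) abort_parameter("both groups need n >= 2")
  if (any(c(sd_x, sd_y) < 0)) abort_parameter("standard deviations must be >= 0")
  out <- t_stats_(mean_x, sd_x, n_x, mean_y, sd_y, n_y, var_equal = var_equal)
  if (anyNA(out$statistic)) {
    abort_degenerate("zero pooled variance: the t statistic is undefined")
  }
  out
}

#' Two-sample t test on raw samples
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @inheritParams t_from_summary
#' @return A one-row tibble as in [t_from_summary()].
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) abort_parameter("both samples need n >= 2")
  t_from_summary(mean(x), stats::sd(x), length(x),
                 mean(y), stats::sd(y), length(y), var_equal = var_equal)
}

#' Pearson chi-square test for a 2x2 table
#'
#' @param x 2x2 matrix of non-negative counts with positive margins.
#' @param correct Apply Yates' continuity correction (default FALSE, the
#'   plain Pearson statistic).
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_square_2x2 <- function(x, correct = FALSE) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2L, 2L))) abort_parameter("`x` must be a 2x2 table")
  if (any(x < 0)) abort_parameter("counts must be non-negative")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    abort_degenerate("chi-square undefined: a table margin is zero")
  }
  res <- suppressWarnings(stats::chisq.test(x, correct = correct))
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = unname(res$p.value))
}

#' Compare every radiomic feature between carcinoma and the benign groups
#'
#' Per phase and per feature, a two-sample t test of the positive group
#' (default `"ACC"`) against all remaining subjects pooled. No
#' multiple-testing adjustment is applied by default; `p_adjust = "BH"`
#' switches on Benjamini-Hochberg adjusted p values in an extra column.
#'
#' @param data Cohort tibble with `group`, `phase` and feature columns.
#' @param features Feature columns to test; defaults to the intersection of
#'   [radiomic_feature_names()] with the columns of `data`.
#' @param positive Group level tested against the pooled rest.
#' @param var_equal Pooled-variance t (default) or Welch.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Tibble with one row per (phase, feature): group summaries,
#'   `statistic`, `df`, `p_value` (and `p_adjusted` when requested).
#'   Features with zero pooled variance get `NA` statistics with a warning.
#' @export
compare_features <- function(data, features = NULL, positive = "ACC",
                             var_equal = TRUE, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!all(c("group", "phase") %in% names(data))) {
    abort_schema("`data` must have `group` and `phase` columns")
  }
  features <- features %||% intersect(radiomic_feature_names(), names(data))
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols) > 0 || length(features) == 0) {
    abort_schema(paste0("missing feature columns: ",
                        paste(if (length(missing_cols)) missing_cols else "(all)",
                              collapse = ", ")))
  }
  if (!any(data$group == positive) || all(data$group == positive)) {
    abort_degenerate("need subjects both inside and outside the positive group")
  }

  out <- purrr::map(unique(data$phase), function(ph) {
    d <- data[data$phase == ph, , drop = FALSE]
    pos <- d$group == positive
    x <- as.matrix(d[pos, features, drop = FALSE])
    y <- as.matrix(d[!pos, features, drop = FALSE])
    mx <- colMeans(x); my <- colMeans(y)
    sx <- apply(x, 2, stats::sd); sy <- apply(y, 2, stats::sd)
    res <- t_stats_(mx, sx, nrow(x), my, sy, nrow(y), var_equal = var_equal)
    dplyr::bind_cols(
      tibble(phase = ph, feature = features,
             mean_positive = unname(mx), sd_positive = unname(sx), n_positive = nrow(x),
             mean_other = unname(my), sd_other = unname(sy), n_other = nrow(y)),
      res
    )
  }) |> dplyr::bind_rows()

  if (anyNA(out$statistic)) {
    warn("some features have zero pooled variance; their t statistics are NA")
  }
  if (p_adjust == "BH") {
    out <- dplyr::mutate(out, p_adjusted = stats::p.adjust(.data$p_value, "BH"),
                         .by = "phase")
  }
  out
}

#' Select the features that discriminate carcinoma from the benign groups
#'
#' Keeps the (phase, feature) pairs whose carcinoma-versus-rest t test has
#' `p_value < alpha` (strict), ordered by phase and ascending p.
#'
#' @inheritParams compare_features
#' @param alpha Selection level (default 0.05). `alpha = 0` selects nothing.
#' @param ... Passed on to [compare_features()].
#' @return Tibble of selected rows in the format of [compare_features()].
#' @export
select_features <- function(data, alpha = 0.05, ...) {
  if (alpha < 0 || alpha > 1) abort_parameter("`alpha` must lie in [0, 1]")
  compare_features(data, ...) |>
    dplyr::filter(!is.na(.data$p_value), .data$p_value < alpha) |>
    dplyr::arrange(.data$phase, .data$p_value)
}
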