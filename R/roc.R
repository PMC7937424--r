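# Empirical ROC analysis with Youden-index cut-off selection.

#' ROC curve, AUC and Youden-index cut-off
#'
#' Builds the empirical ROC of a continuous score against binary labels.
#' Candidate thresholds are the midpoints between adjacent distinct score
#' values (plus -Inf and +Inf), so the reported optimal cut-off falls
#' halfway between the two scores it separates. The orientation is chosen
#' so that AUC >= 0.5 and is recorded: `">"` means higher scores indicate
#' the positive class. AUC is computed by the trapezoidal rule, which for
#' the empirical curve equals the Mann-Whitney pairwise statistic (ties
#' counted 1/2). The Youden cut-off maximizes sensitivity + specificity - 1;
#' if several thresholds attain the maximum, the lowest (on the oriented
#' scale) is reported.
#'
#' @param scores Numeric score per subject.
#' @param labels Binary class per subject (factor, character or logical).
#' @param positive Label value treated as positive. Defaults to `TRUE` for
#'   logical labels, otherwise to the last factor level.
#' @return An object of class `roc_result`: `curve` (tibble of threshold,
#'   sensitivity, specificity, fpr), `auc`, `youden_cutoff`,
#'   `youden_sensitivity`, `youden_specificity`, `orientation`, `positive`,
#'   `n_positive`, `n_negative`.
#' @export
roc_youden <- function(scores, labels, positive = NULL) {
  scores <- as.numeric(scores)
  if (anyNA(scores) || anyNA(labels)) abort_parameter("scores and labels must not contain NA")
  if (is.logical(labels)) {
    positive <- positive %||% TRUE
    lab <- labels
  } else {
    labels <- as.factor(labels)
    positive <- positive %||% levels(labels)[nlevels(labels)]
    lab <- labels == positive
  }
  n1 <- sum(lab)
  n0 <- sum(!lab)
  if (n1 == 0 || n0 == 0) abort_degenerate("both classes must be present for a ROC curve")

  # orientation by Mann-Whitney
  r <- rank(scores)
  auc_raw <- (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  orientation <- if (auc_raw >= 0.5) ">" else "<"
  s <- if (orientation == ">") scores else -scores

  us <- sort(unique(s))
  thr <- c(-Inf, if (length(us) > 1) (us[-1] + us[-length(us)]) / 2, Inf)
  sens <- vapply(thr, function(ct) sum(s[lab] > ct) / n1, numeric(1))
  spec <- vapply(thr, function(ct) sum(s[!lab] <= ct) / n0, numeric(1))
  curve <- tibble(threshold = if (orientation == ">") thr else -thr,
                  sensitivity = sens, specificity = spec, fpr = 1 - spec)

  o <- order(curve$fpr, curve$sensitivity)
  fpr <- curve$fpr[o]
  tpr <- curve$sensitivity[o]
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)

  j <- sens + spec - 1
  best <- which(j == max(j))[1]  # thresholds ascend, so [1] is the lowest

  structure(
    list(curve = curve, auc = auc,
         youden_cutoff = curve$threshold[best],
         youden_sensitivity = sens[best],
         youden_specificity = spec[best],
         orientation = orientation, positive = positive,
         n_positive = n1, n_negative = n0),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%d pos / %d neg, orientation %s)\n",
              x$auc, x$n_positive, x$n_negative, x$orientation))
  cat(sprintf("  Youden cut-off %.4g: sensitivity %.3f, specificity %.3f\n",
              x$youden_cutoff, x$youden_sensitivity, x$youden_specificity))
  invisible(x)
}

#' @describeIn roc_youden Threshold-level ROC coordinates as a tibble.
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @describeIn roc_youden One-row summary: AUC and the Youden operating point.
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, youden_cutoff = x$youden_cutoff,
         youden_sensitivity = x$youden_sensitivity,
         youden_specificity = x$youden_specificity,
         orientation = x$orientation,
         n_positive = x$n_positive, n_negative = x$n_negative)
}

#' @describeIn roc_youden ROC curve plot (sensitivity against 1 - specificity).
#' @param object A `roc_result`.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::annotate("point",
                      x = 1 - object$youden_specificity, y = object$youden_sensitivity,
                      colour = "red", size = 2) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f; Youden cut-off = %.4g",
                                  object$auc, object$youden_cutoff)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
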