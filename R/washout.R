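# Washout densitometry: the conventional-radiology arm of the analysis.

#' Absolute contrast washout
#'
#' `100 * (enhanced - delayed) / (enhanced - unenhanced)`, the percentage of
#' the contrast enhancement lost between the enhanced and delayed phases.
#' Invariant to adding a constant to all three HU values.
#'
#' @param hu_enhanced,hu_delayed,hu_unenhanced Mean VOI densitometry (HU) in
#'   the enhanced, delayed and unenhanced phases. Vectorized.
#' @return Washout in per cent.
#' @export
absolute_washout <- function(hu_enhanced, hu_delayed, hu_unenhanced) {
  denom <- hu_enhanced - hu_unenhanced
  if (any(denom == 0)) {
    abort_washout("absolute washout undefined: enhanced and unenhanced HU are equal")
  }
  100 * (hu_enhanced - hu_delayed) / denom
}

#' Relative contrast washout
#'
#' `100 * (enhanced - delayed) / enhanced`.
#'
#' @inheritParams absolute_washout
#' @return Washout in per cent.
#' @export
relative_washout <- function(hu_enhanced, hu_delayed) {
  if (any(hu_enhanced == 0)) {
    abort_washout("relative washout undefined: enhanced HU is zero")
  }
  100 * (hu_enhanced - hu_delayed) / hu_enhanced
}

#' Rule-based benign/indeterminate classification of a lesion
#'
#' Applies the conventional adrenal CT criteria with strict inequalities:
#' a lesion shows a benign pattern iff its unenhanced attenuation is below
#' 10 HU (lipid-rich) or both washout criteria are met (absolute > 60 per
#' cent and relative > 40 per cent). Everything else is indeterminate.
#' Lesion size does not change the class; it is reported separately as an
#' advisory flag by [washout_table()].
#'
#' @param hu_unenhanced Unenhanced mean densitometry (HU).
#' @param absolute_washout,relative_washout Washout percentages.
#' @return Factor with levels `benign_pattern`, `indeterminate`. Vectorized.
#' @export
classify_washout <- function(hu_unenhanced, absolute_washout, relative_washout) {
  benign <- hu_unenhanced < 10 | (absolute_washout > 60 & relative_washout > 40)
  factor(ifelse(benign, "benign_pattern", "indeterminate"),
         levels = c("benign_pattern", "indeterminate"))
}

#' Washout densitometry for a table of lesions
#'
#' Takes a per-lesion data frame with phase-wise mean densitometry columns
#' and appends absolute/relative washout, the three conventional flags, the
#' rule-based classification, and (if a size column is present) the >= 40 mm
#' size advisory.
#'
#' @param data Data frame with columns `hu_unenhanced`, `hu_enhanced`,
#'   `hu_delayed` and optionally `size_mm`.
#' @return The input as a tibble with columns `absolute_washout`,
#'   `relative_washout`, `lipid_rich`, `high_absolute_washout`,
#'   `high_relative_washout`, `classification` (and `large_lesion` when
#'   `size_mm` is present) appended.
#' @export
washout_table <- function(data) {
  needed <- c("hu_unenhanced", "hu_enhanced", "hu_delayed")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort_schema(paste0("missing washout columns: ", paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(data)
  out <- dplyr::mutate(
    out,
    absolute_washout = absolute_washout(.data$hu_enhanced, .data$hu_delayed, .data$hu_unenhanced),
    relative_washout = relative_washout(.data$hu_enhanced, .data$hu_delayed),
    lipid_rich = .data$hu_unenhanced < 10,
    high_absolute_washout = .data$absolute_washout > 60,
    high_relative_washout = .data$relative_washout > 40,
    classification = classify_washout(.data$hu_unenhanced, .data$absolute_washout,
                                      .data$relative_washout)
  )
  if ("size_mm" %in% names(out)) {
    out <- dplyr::mutate(out, large_lesion = .data$size_mm >= 40)
  }
  out
}
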