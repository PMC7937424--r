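#' Grey-level quantization of a VOI
#'
#' Uniformly bins the HU values of a VOI into `n_grey` grey levels spanning
#' `[min, max]` of the sample. The maximum value maps to level `n_grey`; a
#' constant-valued VOI maps entirely to level 1. All second-order (GLCM/RLM)
#' features are computed on these levels, which makes them invariant to
#' adding a constant HU offset to the whole VOI.
#'
#' @param sample A `voi_sample` from [extract_voi()].
#' @param n_grey Number of grey levels (>= 2). Default 32.
#'
#' @return An object of class `quantized_voi` with elements `levels`
#'   (integer vector aligned with `sample$values`), `n_grey`, `bin_edges`
#'   (`n_grey + 1` HU values), `coords` and `grid_dim`.
#' @export
quantize_voi <- function(sample, n_grey = 32L) {
  stopifnot(inherits(sample, "voi_sample"))
  n_grey <- as.integer(n_grey)
  if (is.na(n_grey) || n_grey < 2L) abort_parameter("`n_grey` must be an integer >= 2")
  v <- sample$values
  if (length(v) == 0L) abort_empty_voi("cannot quantize an empty VOI")
  lo <- min(v)
  hi <- max(v)
  if (hi > lo) {
    levels <- pmin(floor((v - lo) / (hi - lo) * n_grey) + 1L, n_grey)
  } else {
    levels <- rep(1L, length(v))
  }
  structure(
    list(levels = as.integer(levels), n_grey = n_grey,
         bin_edges = seq(lo, hi, length.out = n_grey + 1L),
         coords = sample$coords, grid_dim = sample$grid_dim),
    class = "quantized_voi"
  )
}
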