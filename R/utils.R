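# Condition helpers. Every error raised by the package carries a subclass of
# "adrenomics_error" so callers (and tests) can branch on the failure kind
# rather than on message text.

adrx_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "adrenomics_error"))
}

abort_geometry <- function(message) adrx_abort(message, "adrenomics_error_geometry")
abort_empty_voi <- function(message) adrx_abort(message, "adrenomics_error_empty_voi")
abort_parameter <- function(message) adrx_abort(message, "adrenomics_error_parameter")
abort_degenerate <- function(message) adrx_abort(message, "adrenomics_error_degenerate")
abort_io <- function(message) adrx_abort(message, "adrenomics_error_io")
abort_metadata <- function(message) adrx_abort(message, "adrenomics_error_metadata")
abort_spec <- function(message) adrx_abort(message, "adrenomics_error_spec")
abort_schema <- function(message) adrx_abort(message, "adrenomics_error_schema")
abort_washout <- function(message) adrx_abort(message, "adrenomics_error_washout")

ct_phases <- function() c("unenhanced", "arterial", "venous", "delayed")

# population standard deviation (divisor n)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# base-2 entropy of a probability vector, with 0 * log2(0) := 0
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
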