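#' @importFrom rlang abort warn %||%
#' @importFrom stats rnbinom rpois runif rbinom pchisq pf
NULL

# Round half away from zero (base round() is banker's rounding and would give
# e.g. round(0.5) == 0, which does not reproduce printed table cells).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# The six segment labels, in the default precedence order used by the
# assignment rules (highest precedence first is the reverse of this display
# order; see segmentation_config()).
segment_levels <- function() {
  c("mostly_healthy", "serious_acute", "stable_chronic",
    "complex_no_freq", "complex_freq", "end_of_life")
}

default_precedence <- function() {
  c("end_of_life", "complex_freq", "complex_no_freq",
    "serious_acute", "stable_chronic", "mostly_healthy")
}

segment_factor <- function(x) {
  factor(x, levels = segment_levels())
}

assert_segments <- function(x, what = "segment") {
  bad <- setdiff(unique(as.character(x)), segment_levels())
  if (length(bad) > 0) {
    abort(sprintf("unknown %s label(s): %s", what, paste(bad, collapse = ", ")))
  }
  invisible(x)
}
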