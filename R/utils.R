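#' @keywords internal
"_PACKAGE"

# Classed errors so callers can distinguish malformed files from bad arguments.
abort_rula <- function(message, class, call. = FALSE) {
  stop(structure(
    class = c(class, "rula_error", "error", "condition"),
    list(message = message, call = if (isTRUE(call.)) sys.call(-1))
  ))
}

abort_format    <- function(msg) abort_rula(msg, "rula_format_error")
abort_parse     <- function(msg) abort_rula(msg, "rula_parse_error")
abort_integrity <- function(msg) abort_rula(msg, "rula_integrity_error")
abort_input     <- function(msg) abort_rula(msg, "rula_input_error")
abort_config    <- function(msg) abort_rula(msg, "rula_config_error")

#' Round half away from zero
#'
#' Reporting-layer rounding used for printed tables: ties round up (97.425 ->
#' 97.43), unlike [round()]'s round-half-even. Applied only when formatting
#' results; all internal computation keeps full precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Significance star coding used in the output tables.
signif_stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "")))
}
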