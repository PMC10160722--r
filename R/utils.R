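#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for printed money and percentage
#' values: 0.5 always rounds away from zero, unlike [base::round()]'s
#' round-half-to-even. Internal computations are never rounded; this is a
#' reporting convention only.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_up(91.25, 1) # 91.3
#' round_half_up(2.345, 2) # 2.35
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  trunc(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) * sign(x) / m
}

# classed conditions -------------------------------------------------------

abort_tdabc <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "tdabcost_error"), ...)
}

stop_invalid_parameter <- function(message) {
  abort_tdabc(message, "tdabcost_invalid_parameter")
}

stop_invalid_input <- function(message) {
  abort_tdabc(message, "tdabcost_invalid_input")
}

stop_missing_reference <- function(message, ids = character()) {
  abort_tdabc(message, "tdabcost_missing_reference", ids = ids)
}

`%||%` <- rlang::`%||%`
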