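#' Round half away from zero
#'
#' Rounds the magnitude of `x` half-up to `digits` decimal places, preserving
#' the sign. This matches the presentation convention of published expression
#' tables (e.g. a fold difference of -2.6381 prints as -2.64), unlike base
#' [round()], which rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' round_half_up(2.645, 2)   # 2.65
#' round_half_up(-2.645, 2)  # -2.65
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# internal: stop() with a call-free message
fail <- function(...) stop(..., call. = FALSE)

# internal: check a scalar/vector is numeric, finite
check_finite_numeric <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    fail(what, " must be finite and numeric")
  }
  invisible(x)
}
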