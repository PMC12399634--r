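#' Round half away from zero
#'
#' Commercial rounding: exact halves move away from zero, so 0.625 becomes
#' 0.63 at two decimals (base [round()] uses banker's rounding and would give
#' 0.62). All tabulated proportions, primary scores, and index values in this
#' package are reported with this rule.
#'
#' A guard of 1e-8 absorbs binary representation error in values that are
#' exact halves in decimal (e.g. the mean of two-decimal scores 24.66/4 =
#' 6.165 is stored slightly below 6.165 in double precision).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @export
#' @examples
#' round_half_up(0.625, 2) # 0.63
#' round_half_up(-0.625, 2) # -0.63
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-8) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ids <- function(msg, ids) {
  stop(sprintf("%s: %s", msg, paste(ids, collapse = ", ")), call. = FALSE)
}
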