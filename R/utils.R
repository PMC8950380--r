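# Shared internal helpers.

#' Round half away from zero
#'
#' Registry reports round percentages with halves going away from zero
#' (so 8.65 -> 8.7 and -8.65 -> -8.7), unlike [base::round()]'s
#' round-half-even. Used by every reported percentage in the package.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @export
round_half_away <- function(x, digits = 1L) {
  stopifnot(is.numeric(x))
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Derive a stage seed from a master seed, keeping the result a valid
# 32-bit integer. Stages are numbered so each is independently rerunnable.
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 1009 + stage * 9973) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
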