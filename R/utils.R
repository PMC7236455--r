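#' Round half away from zero
#'
#' Deterministic half-up rounding at a fixed number of decimal digits, as used
#' when comparing derived rates against values printed at a fixed precision.
#' Base R's `round()` rounds half to even, which cannot reproduce printed
#' clinical summaries such as "40.5%" obtained from 24.8 -> 25 style rounding.
#'
#' @param x numeric vector (non-negative values expected for rates).
#' @param digits integer number of decimal digits.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Pooled (weighted) mean of subgroup means
#'
#' @param n integer vector of subgroup sizes.
#' @param means numeric vector of subgroup means.
#' @return the size-weighted mean.
#' @export
pooled_mean <- function(n, means) {
  stopifnot(length(n) == length(means), all(n > 0))
  sum(n * means) / sum(n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cellloss <- function(msg, class) {
  stop(structure(class = c(class, "cellloss_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
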