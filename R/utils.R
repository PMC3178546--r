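#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; accuracy tables here render
#' percentages with the convention that halves move away from zero
#' (so 88.8889 -> 89, and exactly 96.5 -> 97).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a fraction as a percentage string
#'
#' @param frac fraction in `[0, 1]`.
#' @param digits decimal places (default 2; use 0 for integer percents).
#' @return character vector like `"99.25%"`.
#' @keywords internal
format_percent <- function(frac, digits = 2) {
  paste0(formatC(round_half_away(100 * frac, digits),
                 format = "f", digits = digits), "%")
}

# Structured log line to stderr; data outputs never share this stream.
log_msg <- function(..., level = "INFO") {
  message(sprintf("[getem %s] %s", level, paste0(...)))
}

# Derive a bounded sub-seed from a master seed and an operation tag, so each
# simulator operation consumes an independent, reproducible stream.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 2654435 + h * 97) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
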