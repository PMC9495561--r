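# Small shared helpers.

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero, matching the
#' convention of most published fitness tables (base R's `round()` rounds
#' half to even).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 2).
#' @return numeric vector of the same length.
#' @export
#' @examples
#' round_half_up(34.495)   # 34.50, not 34.49
#' round_half_up(-0.125, 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # tiny nudge so values that are exactly .5 in decimal but stored just
  # below it in binary (34.495 * 100 = 3449.4999...) still round up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("'%s' must be a positive scalar", name), call. = FALSE)
  }
  invisible(x)
}

# standard logistic, used by the neural-network-style equations
sigmoid <- function(z) 1 / (1 + exp(-z))
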