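# Shared helpers: presentation rounding and input checks.

#' Round half away from zero
#'
#' Presentation rounding used throughout: nearest integer, ties away from
#' zero (so 0.5 -> 1, -0.5 -> -1). Base [round()] rounds half to even,
#' which does not match the convention of published burden tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 2.4))
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Stop with a consistent error class so callers/tests can condition on it.
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("preventyll_invalid_input", "error")))
}

stop_lookup <- function(...) {
  stop(errorCondition(paste0(...), class = c("preventyll_lookup_error", "error")))
}

check_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(name, " must be a single finite number")
  }
  if (positive && x <= 0) stop_invalid(name, " must be strictly positive")
  if (nonneg && x < 0) stop_invalid(name, " must be non-negative")
  invisible(x)
}

# 97.5% normal quantile used for all 95% confidence intervals.
z975 <- function() stats::qnorm(0.975)
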