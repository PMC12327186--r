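# Internal helpers: classed error conditions and small numeric utilities.

.stopWith <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

# Validation errors: malformed or out-of-range data.
.stopValidation <- function(msg) .stopWith("ctsValidationError", msg)
# Contract errors: a precondition of an operation is violated.
.stopContract <- function(msg) .stopWith("ctsContractError", msg)
# Parse errors: unreadable cells or files.
.stopParse <- function(msg) .stopWith("ctsParseError", msg)

#' Geometric mean
#'
#' Geometric mean of strictly positive values, computed on the log scale.
#'
#' @param x Numeric vector of positive values.
#' @return A single numeric value.
#' @examples
#' geometricMean(c(16, 25)) # 20
#' @export
geometricMean <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0))
    .stopValidation("geometric mean requires finite, strictly positive values")
  exp(mean(log(x)))
}

# Truncate (floor) to two decimals, the display convention for consensus
# scores. A 1e-9 guard absorbs floating-point dust just below an integer
# hundredth (e.g. 6.999999999 from exp(mean(log(...)))).
.trunc2 <- function(x) floor(x * 100 + 1e-9) / 100

# Sample SD with the n-1 denominator; errors below 2 observations.
.sampleSD <- function(x) {
  if (length(x) < 2L)
    .stopContract("standard deviation undefined for fewer than 2 observations")
  stats::sd(x)
}
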