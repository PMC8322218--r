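#' @keywords internal
"_PACKAGE"

## Shared small helpers.

#' Derive a child RNG seed from a master seed and a counter
#'
#' Linear-congruential mixing keeps every derived seed inside the 32-bit
#' integer range R requires. Used so that per-record / per-iteration draws are
#' functions of (master seed, counter) alone, never of execution order.
#'
#' @param seed master seed (integer).
#' @param counter non-negative integer stream index.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, counter) {
  m <- 2147483647 # 2^31 - 1 (Mersenne prime, classic Lehmer modulus)
  s <- (as.numeric(seed) %% m) * 48271 + as.numeric(counter) * 1000003 + 11
  as.integer(s %% m)
}

#' Round half away from zero
#'
#' Report percentages use conventional half-up rounding (so 3.15 -> 3.2),
#' not the banker's rounding of [base::round()].
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Is `x` a single non-missing value of the given predicate?
.scalar <- function(x, pred) length(x) == 1L && !is.na(x) && pred(x)

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

## Blank-as-missing: CSV round-trips turn NA into "" and back.
.is_missing <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
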