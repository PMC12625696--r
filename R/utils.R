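#' Round half-up on a decimal representation
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (0.5 -> 1, 1.285 -> 1.29 at two decimals), unlike [base::round()] which
#' rounds half to even. Binary-float representation artifacts
#' (e.g. `1.285 * 100 == 128.49999...`) are cleared before the half-up step,
#' so the result matches rounding performed on the printed decimal string.
#'
#' This is the display-rounding convention used throughout the reporting
#' system: sensitivity and similarity to whole percent, FPRA to two decimals,
#' diversity to a whole count.
#'
#' @param x numeric vector.
#' @param digits integer, number of decimal places (default 0).
#' @return numeric vector of the same length.
#' @examples
#' roundHalfUp(74.5)        # 75
#' roundHalfUp(1.285, 2)    # 1.29
#' @export
roundHalfUp <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  z <- abs(x) * 10^digits
  # values at play carry at most a handful of true decimals; clearing beyond
  # six guards the .5 boundary against binary representation error
  z <- round(z, 6)
  sign(x) * floor(z + 0.5) / 10^digits
}

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream. All stochastic operations in the package funnel through this.
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

# shared error helper: consistent condition class for data-level failures
dataError <- function(...) {
  stop(errorCondition(paste0(...), class = c("taxprofileQC_data_error", "error")))
}
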