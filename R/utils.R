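# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero, the convention
#' used for all printed percentages in the trial report (e.g. 5/14 -> 36%).
#' Base [round()] uses banker's rounding and would disagree at .5 ties.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @keywords internal
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# stop() with a consistent prefix for parameter validation failures
.param_error <- function(...) {
  stop(..., call. = FALSE)
}

.check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    .param_error(name, " must be a single finite number")
  }
  if (x < lower || x > upper) {
    .param_error(name, " must be in [", lower, ", ", upper, "]")
  }
  invisible(x)
}

.check_proportion <- function(x, name) .check_number(x, name, 0, 1)

# Deterministic derived seeds, kept below 2^31 so set.seed() accepts them.
.derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 + 7919 * as.numeric(index)) %% 2147483647)
}

# Deterministic string hash in [0, 1); used by the synthetic binding predictor.
.hash_unit <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) {
    h <- (h * 131 + code) %% 2147483647
  }
  ((h * 48271) %% 2147483647) / 2147483647
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
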