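# Cohort-level statistics: printed rates and the standard tests used for all
# correlate-vs-response comparisons.  The test machinery itself is delegated
# to stats:: (wilcox.test, t.test, lm); these wrappers fix the conventions
# (two-sided, exact small-sample Mann-Whitney, sentinels for degenerate
# input) used throughout the report.

#' Integer percentage of a count ratio
#'
#' `round(100 * numerator / denominator)` with ties rounded away from zero,
#' matching the printed-rate style of the trial report (5/14 -> 36).
#'
#' @param numerator,denominator Counts with
#'   `0 <= numerator <= denominator`, `denominator > 0`.
#' @return Integer percent.
#' @export
rate_percent <- function(numerator, denominator) {
  .check_number(numerator, "numerator", lower = 0)
  .check_number(denominator, "denominator")
  if (denominator <= 0) .param_error("degenerate input: denominator is zero")
  if (numerator > denominator) .param_error("numerator exceeds denominator")
  as.integer(round_half_up(100 * numerator / denominator))
}

#' Two-sided Mann-Whitney U comparison by response
#'
#' Compares a per-patient correlate between responders and non-responders.
#' The exact distribution is used when both groups have at most 8
#' observations and the data are tie-free; otherwise the normal approximation
#' with continuity and tie correction.
#'
#' @param values Numeric vector (one value per patient).
#' @param pr_flags Logical vector: TRUE = responder.
#' @return List with `U` (statistic for the responder group), `p`,
#'   `n_responder`, `n_nonresponder`; `U`/`p` are NA (undefined-result
#'   sentinel) when either group is empty after dropping NAs.
#' @export
compare_by_response <- function(values, pr_flags) {
  stopifnot(length(values) == length(pr_flags))
  ok <- !is.na(values) & !is.na(pr_flags)
  x <- values[ok & pr_flags]
  y <- values[ok & !pr_flags]
  if (length(x) == 0L || length(y) == 0L) {
    return(list(U = NA_real_, p = NA_real_, n_responder = length(x),
                n_nonresponder = length(y)))
  }
  exact <- length(x) <= 8L && length(y) <= 8L && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value,
       n_responder = length(x), n_nonresponder = length(y))
}

#' Paired Wilcoxon signed-rank and one-sample t tests
#'
#' The signed-rank test compares post vs pre values pairwise (zero
#' differences dropped, per the standard definition); the one-sample t test
#' compares a log2 fold-change vector against 0.  An all-zero difference
#' vector is an undefined-result sentinel for the signed-rank test (NA); an
#' all-zero fold-change vector returns t-test p = 1 (no evidence of change by
#' convention, since the t statistic is 0/0).
#'
#' @param pre,post Paired vectors (same length >= 2).
#' @param log2fc Fold-change vector for the one-sample test; defaults to
#'   `log2_fc(pre, post)`.
#' @return List with `wilcoxon_p` and `t_p`.
#' @export
paired_and_one_sample_tests <- function(pre, post, log2fc = NULL) {
  stopifnot(length(pre) == length(post), length(pre) >= 2L)
  if (is.null(log2fc)) log2fc <- log2_fc(pre, post)

  d <- post - pre
  wilcoxon_p <- if (all(d == 0)) NA_real_ else {
    suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE,
                                        alternative = "two.sided"))$p.value
  }

  t_p <- if (all(log2fc == 0)) {
    1
  } else if (stats::sd(log2fc) < sqrt(.Machine$double.eps) *
             (abs(mean(log2fc)) + 1)) {
    # constant nonzero shift: no within-sample variance to test against
    NA_real_
  } else {
    stats::t.test(log2fc, mu = 0)$p.value
  }
  list(wilcoxon_p = wilcoxon_p, t_p = t_p)
}

#' Ordinary least squares fit with goodness-of-fit test
#'
#' @param x,y Numeric vectors, `length >= 3`, `var(x) > 0`.
#' @return List with `slope`, `intercept`, `r_squared`, and `p` (F test of
#'   nonzero slope; 0 for an exact fit).
#' @export
regression_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) .param_error("regression requires n >= 3")
  if (stats::var(x) == 0) .param_error("degenerate input: x has zero variance")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  r2 <- sm$r.squared
  fstat <- sm$fstatistic
  p <- if (is.null(fstat) || !is.finite(fstat[1])) {
    if (isTRUE(all.equal(r2, 1))) 0 else NA_real_
  } else {
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  }
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, p = p)
}
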