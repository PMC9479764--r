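# Pathologic and radiographic response scoring.
#
# pTR is reported as percent tumor regression: 100 minus the percentage of
# residual viable tumor within the tumor bed, area-weighted over all scored
# slides and rounded to the nearest integer percent.  Response classes follow
# the standardized immune-related definitions: pCR = 100, MPR = 90-99,
# pPR = 50-89, NR < 50; a PR for correlative purposes is pTR >= 50.

#' Pathologic tumor response from slide areas
#'
#' Aggregates per-slide viable-tumor and tumor-bed surface areas for one
#' patient/site and returns the pathologic tumor response as an integer
#' percent regression.  Weighting by slide bed area is implicit in summing
#' areas before dividing.
#'
#' @param slides data.frame with columns `viable_area_mm2` and `bed_area_mm2`
#'   (one row per slide; all rows the same patient and site).
#' @return Integer pTR in 0..100 (`100 * (1 - sum(viable) / sum(bed))`,
#'   rounded half away from zero).
#' @export
compute_ptr <- function(slides) {
  if (!is.data.frame(slides) || nrow(slides) == 0L) {
    .param_error("slides must be a nonempty data.frame")
  }
  v <- slides$viable_area_mm2
  b <- slides$bed_area_mm2
  if (any(!is.finite(v)) || any(!is.finite(b)) || any(v < 0) || any(b < 0)) {
    .param_error("slide areas must be finite and >= 0")
  }
  if (any(v > b + 1e-9)) {
    .param_error("viable_area_mm2 cannot exceed bed_area_mm2")
  }
  if (sum(b) <= 0) {
    .param_error("degenerate input: total tumor-bed area is zero")
  }
  as.integer(round_half_up(100 * (1 - sum(v) / sum(b))))
}

#' Classify a pathologic tumor response
#'
#' @param ptr Integer pTR percent in 0..100.
#' @param possible_ln_cr Whether this (lymph-node) response is a possible CR:
#'   suspicious node pre-treatment found pathologically negative.
#' @return List with `ptr_percent`, `class` (`"pCR"`, `"MPR"`, `"pPR"`,
#'   `"NR"`), `pr_flag` (pTR >= 50) and `possible_ln_cr`.
#' @export
classify_response <- function(ptr, possible_ln_cr = FALSE) {
  .check_number(ptr, "ptr", 0, 100)
  cls <- if (ptr == 100) "pCR" else if (ptr >= 90) "MPR" else
    if (ptr >= 50) "pPR" else "NR"
  list(ptr_percent = as.integer(ptr), class = cls, pr_flag = ptr >= 50,
       possible_ln_cr = isTRUE(possible_ln_cr))
}

#' Discordance between primary-tumor and lymph-node responses
#'
#' Discordant means the two site responses differ by more than 20 percentage
#' points; a possible LN complete response counts as 100.
#'
#' @param primary_ptr Primary-tumor pTR percent.
#' @param ln_ptr LN pTR percent (ignored when `ln_possible_cr` is TRUE).
#' @param ln_possible_cr Treat the LN response as a possible CR (100).
#' @return TRUE if discordant.
#' @export
classify_discordance <- function(primary_ptr, ln_ptr, ln_possible_cr = FALSE) {
  .check_number(primary_ptr, "primary_ptr", 0, 100)
  if (isTRUE(ln_possible_cr)) ln_ptr <- 100
  .check_number(ln_ptr, "ln_ptr", 0, 100)
  abs(primary_ptr - ln_ptr) > 20
}

# normalize a lesion table so length >= width, summing products over lesions
.lesion_volume <- function(lesions) {
  l <- pmax(lesions$length_mm, lesions$width_mm)
  w <- pmin(lesions$length_mm, lesions$width_mm)
  if (any(!is.finite(l)) || any(l <= 0) || any(w <= 0)) {
    .param_error("lesion measurements must be finite and > 0")
  }
  sum(l * w)
}

#' Radiographic volume change
#'
#' Lesion "volume" is the product of the longest perpendicular bidimensional
#' measurements (mm^2); multi-lesion sites sum volumes before comparing.
#'
#' @param pre,post data.frames of lesions with columns `length_mm`,
#'   `width_mm` (normalized so length >= width on ingest).
#' @return Percent change `100 * (post - pre) / pre`.
#' @export
volume_change <- function(pre, post) {
  v_pre <- .lesion_volume(pre)
  v_post <- .lesion_volume(post)
  if (v_pre <= 0) .param_error("degenerate input: pre-treatment volume is zero")
  100 * (v_post - v_pre) / v_pre
}
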