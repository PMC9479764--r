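# ELISpot response calling.
#
# Each condition is assayed in technical duplicate; mean spot counts are the
# working quantity.  A response is "detected" when the mean count is greater
# than 0, "positive" when the post-treatment mean is 5 or higher, and
# "increased" when the post - pre difference in means exceeds 5 spots.

.elispot_mean <- function(row) {
  if (is.null(row)) return(NA_real_)
  reps <- c(row$rep1, row$rep2)
  if (any(!is.finite(reps)) || any(reps < 0)) {
    .param_error("replicate counts must be finite and >= 0")
  }
  mean(reps)
}

#' Classify one ELISpot condition
#'
#' @param pre,post Lists/rows with `rep1` and `rep2` duplicate spot counts
#'   for the same patient and condition; either may be `NULL` (missing
#'   timepoint), in which case the dependent flags are NA.
#' @return List with `pre_mean`, `post_mean`, `detected_pre`,
#'   `detected_post`, `positive` (post mean >= 5) and `increased`
#'   (post mean - pre mean > 5).
#' @export
classify_condition <- function(pre, post) {
  pre_mean <- .elispot_mean(pre)
  post_mean <- .elispot_mean(post)
  list(pre_mean = pre_mean,
       post_mean = post_mean,
       detected_pre = if (is.na(pre_mean)) NA else pre_mean > 0,
       detected_post = if (is.na(post_mean)) NA else post_mean > 0,
       positive = if (is.na(post_mean)) NA else post_mean >= 5,
       increased = if (is.na(pre_mean) || is.na(post_mean)) NA else
         (post_mean - pre_mean) > 5)
}

#' Classify a whole ELISpot plate
#'
#' @param plate data.frame with columns `patient_id`, `condition`,
#'   `condition_type` (`"neoepitope"`, `"cef"`, `"e7_control"`,
#'   `"background"`), `timepoint` (`"pre"`/`"post"`), `rep1`, `rep2`.
#' @param subtract_background Subtract the matching timepoint's no-peptide
#'   background mean from every condition mean, floored at 0 (off by
#'   default; raw means are reported).
#' @return data.frame of per-condition flags (one row per condition).
#' @export
classify_plate <- function(plate, subtract_background = FALSE) {
  out <- list()
  for (pid in unique(plate$patient_id)) {
    pp <- plate[plate$patient_id == pid, , drop = FALSE]
    bg <- c(pre = 0, post = 0)
    if (subtract_background) {
      for (tp in c("pre", "post")) {
        b <- pp[pp$condition_type == "background" & pp$timepoint == tp, ,
                drop = FALSE]
        if (nrow(b) == 1L) bg[[tp]] <- .elispot_mean(b)
      }
    }
    for (cond in unique(pp$condition)) {
      rows <- pp[pp$condition == cond, , drop = FALSE]
      grab <- function(tp) {
        r <- rows[rows$timepoint == tp, , drop = FALSE]
        if (nrow(r) == 0L) return(NULL)
        list(rep1 = r$rep1[1], rep2 = r$rep2[1])
      }
      fl <- classify_condition(grab("pre"), grab("post"))
      if (subtract_background) {
        fl$pre_mean <- max(0, fl$pre_mean - bg[["pre"]])
        fl$post_mean <- max(0, fl$post_mean - bg[["post"]])
        fl$detected_pre <- if (is.na(fl$pre_mean)) NA else fl$pre_mean > 0
        fl$detected_post <- if (is.na(fl$post_mean)) NA else fl$post_mean > 0
        fl$positive <- if (is.na(fl$post_mean)) NA else fl$post_mean >= 5
        fl$increased <- if (is.na(fl$pre_mean) || is.na(fl$post_mean)) NA else
          (fl$post_mean - fl$pre_mean) > 5
      }
      out[[length(out) + 1L]] <- data.frame(
        patient_id = pid, condition = cond,
        condition_type = rows$condition_type[1],
        pre_mean = fl$pre_mean, post_mean = fl$post_mean,
        detected_pre = fl$detected_pre, detected_post = fl$detected_post,
        positive = fl$positive, increased = fl$increased,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-patient ELISpot aggregates
#'
#' @param flags Per-condition flags (one patient) from [classify_plate()].
#' @return List with `n_positive_neoepitopes` (positive neoepitope wells),
#'   `cumulative_spot_count` (sum of post-treatment means over all
#'   neoepitope wells), and `cef_positive` (viral recall-antigen control;
#'   never counted as a neoepitope).
#' @export
patient_aggregates <- function(flags) {
  stopifnot(length(unique(flags$patient_id)) <= 1L)
  neo <- flags[flags$condition_type == "neoepitope", , drop = FALSE]
  cef <- flags[flags$condition_type == "cef", , drop = FALSE]
  list(
    n_positive_neoepitopes = sum(neo$positive, na.rm = TRUE),
    cumulative_spot_count = sum(neo$post_mean, na.rm = TRUE),
    cef_positive = nrow(cef) > 0L && any(cef$positive, na.rm = TRUE)
  )
}
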