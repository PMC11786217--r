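# Predictability of the 1-year outcome.
#
# The final outcome of a lesion is defined as the category of the first
# follow-up after 12 months (365 days, strict). A good assessment method
# should "see" that final category early: the detection day is the first
# follow-up whose category equals the final one. Its bounds are the first
# follow-up day (the final response was visible immediately) and the first
# follow-up after one year (it was never visible earlier).

#' One-year response of a lesion
#'
#' The category of the earliest follow-up strictly beyond 365 days.
#' Lesions without such a follow-up are excluded from the outcome analysis;
#' the error condition (`ranobm_no_one_year_followup`) signals the
#' filtering.
#'
#' @param seq A [response_sequence] (follow-up times in days carried
#'   inside), or a character/factor vector with `times` supplied.
#' @param times Follow-up days, if `seq` is a plain vector.
#' @return Single category string.
#' @export
one_year_response <- function(seq, times = NULL) {
  if (inherits(seq, "response_sequence")) {
    times <- seq$times
    cats <- as.character(seq$categories)
  } else {
    cats <- as.character(seq)
  }
  if (length(times) != length(cats)) {
    stop_ranobm("times and categories must align", "ranobm_invalid_series")
  }
  beyond <- which(times > 365)
  if (length(beyond) == 0L) {
    stop_ranobm("lesion has no follow-up after 1 year; excluded",
                "ranobm_no_one_year_followup")
  }
  cats[min(beyond)]
}

#' Day on which the final response is first observed
#'
#' The earliest follow-up, up to and including the first follow-up after
#' one year, whose category equals the final (1-year) category. The
#' defining follow-up itself always matches, so the value is well defined.
#'
#' @inheritParams one_year_response
#' @param final_category The category from [one_year_response]; computed if
#'   missing.
#' @return Day since treatment.
#' @export
time_to_outcome <- function(seq, times = NULL, final_category = NULL) {
  if (inherits(seq, "response_sequence")) {
    times <- seq$times
    cats <- as.character(seq$categories)
  } else {
    cats <- as.character(seq)
  }
  if (is.null(final_category)) {
    final_category <- one_year_response(cats, times)
  }
  idx_def <- min(which(times > 365))
  window <- seq_len(idx_def)
  times[window][match(final_category, cats[window])]
}

#' Cohort-level summary of outcome-detection times
#'
#' For every eligible lesion (follow-up beyond one year) and every
#' assessment method, computes the detection day of the one-year response;
#' summarizes per method (mean, median, sd, n) and reports pairwise paired
#' Wilcoxon p-values between methods over the common lesions.
#'
#' @param sequences Named list: `sequences[[method]]` is a list of
#'   [response_sequence]s, keyed consistently by lesion across methods.
#' @return List with `records` (lesion x method detection days),
#'   `summary` (per-method data.frame), and `pairwise_p` (matrix).
#' @export
cohort_outcome_summary <- function(sequences) {
  methods <- names(sequences)
  if (is.null(methods) || length(methods) == 0L) {
    stop_ranobm("need a named list of per-method sequences",
                "ranobm_invalid_value")
  }
  recs <- list()
  for (m in methods) {
    for (s in sequences[[m]]) {
      day <- tryCatch({
        fc <- one_year_response(s)
        time_to_outcome(s, final_category = fc)
      }, ranobm_no_one_year_followup = function(e) NA_real_)
      recs[[length(recs) + 1L]] <- data.frame(
        lesion_id = s$lesion_id, method = m, detection_day = day,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  records <- records[!is.na(records$detection_day), , drop = FALSE]
  if (nrow(records) == 0L) {
    stop_ranobm("no lesion has a follow-up beyond 1 year",
                "ranobm_invalid_value")
  }
  summ <- do.call(rbind, lapply(split(records, records$method), function(d) {
    data.frame(method = d$method[1], n = nrow(d),
               mean_day = mean(d$detection_day),
               median_day = stats::median(d$detection_day),
               sd_day = stats::sd(d$detection_day),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  wide <- stats::reshape(records, idvar = "lesion_id", timevar = "method",
                         direction = "wide")
  pw <- matrix(NA_real_, length(methods), length(methods),
               dimnames = list(methods, methods))
  for (i in seq_along(methods)) {
    for (j in seq_along(methods)) {
      if (i >= j) next
      a <- wide[[paste0("detection_day.", methods[i])]]
      b <- wide[[paste0("detection_day.", methods[j])]]
      if (is.null(a) || is.null(b)) next
      keep <- !is.na(a) & !is.na(b)
      if (sum(keep) >= 2) {
        pw[i, j] <- pw[j, i] <-
          suppressWarnings(paired_difference_test(a[keep], b[keep]))
      }
    }
  }
  list(records = records, summary = summ, pairwise_p = pw)
}
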