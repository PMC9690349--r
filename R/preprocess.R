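#' Eligibility and inclusion filtering of a raw sensor series
#'
#' Two rules are applied to each raw skin-temperature record before
#' recurrence analysis. First, a subject-setting record is eligible only if
#' fewer than `exclusion_fraction` of its values fall below `threshold_c`
#' (an armpit sensor mostly reading below 30 degC was detached, not
#' measuring skin). Second, only values at or above the threshold enter the
#' analysed series; sub-threshold values are dropped in place and the
#' retained values are treated as a contiguous sequence, with the drop
#' positions recorded for audit.
#'
#' @param series a [temperature_series].
#' @param threshold_c inclusion threshold in degrees Celsius (default 30).
#' @param exclusion_fraction record excluded when the fraction of
#'   sub-threshold values reaches this proportion (default 0.80).
#' @return a list with `series` (the filtered [temperature_series]; `NULL`
#'   when ineligible) and `report`, a one-row data frame with columns
#'   `subject_id`, `setting`, `n_raw`, `n_below_threshold`, `fraction_below`,
#'   `eligible`, `n_retained`, `n_gaps`.
#' @export
apply_inclusion_filter <- function(series, threshold_c = 30,
                                   exclusion_fraction = 0.80) {
  stopifnot(inherits(series, "temperature_series"))
  n_raw <- length(series$values)
  if (n_raw == 0L) stop("empty series")
  below <- series$values < threshold_c
  n_below <- sum(below)
  frac <- n_below / n_raw
  eligible <- frac < exclusion_fraction
  keep <- which(!below)
  # runs of dropped values = gaps introduced by the filter
  n_gaps <- if (length(keep)) sum(diff(keep) > 1) + as.integer(keep[1] > 1) else 0L
  report <- data.frame(subject_id = series$subject_id,
                       setting = series$setting,
                       n_raw = n_raw,
                       n_below_threshold = n_below,
                       fraction_below = frac,
                       eligible = eligible,
                       n_retained = length(keep),
                       n_gaps = n_gaps,
                       stringsAsFactors = FALSE)
  out <- NULL
  if (eligible && length(keep)) {
    out <- temperature_series(series$values[keep],
                              subject_id = series$subject_id,
                              setting = series$setting)
  }
  list(series = out, report = report)
}

#' Cohort-level eligibility summary
#'
#' A subject enters the paired analysis only when every one of its
#' subject-setting records is eligible.
#'
#' @param reports data frame of filter reports (one row per subject-setting),
#'   as produced by [apply_inclusion_filter()].
#' @return a list with `by_subject` (data frame: `subject_id`, `eligible`)
#'   and counts `n_subjects`, `n_eligible`.
#' @export
summarize_cohort_eligibility <- function(reports) {
  if (!is.data.frame(reports) || nrow(reports) == 0L)
    stop("no filter reports supplied")
  key <- paste(reports$subject_id, reports$setting)
  if (anyDuplicated(key))
    stop(sprintf("duplicated subject-setting report: %s", key[duplicated(key)][1]))
  agg <- tapply(reports$eligible, reports$subject_id, all)
  by_subject <- data.frame(subject_id = names(agg),
                           eligible = as.logical(agg),
                           stringsAsFactors = FALSE)
  by_subject <- by_subject[order(by_subject$subject_id), , drop = FALSE]
  rownames(by_subject) <- NULL
  list(by_subject = by_subject,
       n_subjects = nrow(by_subject),
       n_eligible = sum(by_subject$eligible))
}

#' Analyte-level outlier exclusion
#'
#' Optional rule flagging subjects whose mean analyte concentration exceeds
#' a cutoff (e.g. implausibly high leptin pointing to an assay problem).
#' Off by default in the pipeline; no cutoff is pre-set.
#'
#' @param hormones hormone table (see [read_hormone_table()]).
#' @param analyte analyte column name.
#' @param cutoff subjects with mean concentration above this are flagged.
#' @return character vector of flagged subject ids.
#' @export
flag_analyte_outliers <- function(hormones, analyte, cutoff) {
  stopifnot(analyte %in% names(hormones), is.numeric(cutoff))
  means <- tapply(hormones[[analyte]], hormones$subject_id, mean, na.rm = TRUE)
  names(means)[means > cutoff]
}
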