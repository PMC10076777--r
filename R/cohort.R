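#' Apply cohort eligibility rules to a clinical table
#'
#' Enforces the study's recurrence-cohort definition on a clinical tibble:
#'
#' * recurrences earlier than `min_recurrence_months` (default 2) months after
#'   surgery are excluded as likely residual disease;
#' * recurrences later than `recurrence_window_months` (default 60) months
#'   fall outside the recurrence-group definition and are recoded as censored
#'   at the window boundary;
#' * optionally, non-recurrence samples that received chemo- or radiotherapy
#'   are excluded, removing treatment effects from the reference group. The
#'   flag deliberately leaves treated *recurrence* samples in place.
#'
#' The filter is idempotent: applying it to an already-filtered table changes
#' nothing.
#'
#' @param clinical Clinical tibble (`sample_id`, `time_months`, `event`,
#'   optional `treatment_flag`).
#' @param exclude_treated_norecurrence Drop event-free samples with
#'   `treatment_flag` in `{chemo, radio}` (default `FALSE`).
#' @param min_recurrence_months Early-recurrence exclusion boundary in months.
#' @param recurrence_window_months Recurrence-group window in months.
#' @return Filtered tibble with attribute `"exclusions"`: a tibble listing
#'   every removed or recoded row and the rule that fired. Retrieve it with
#'   [cohort_exclusions()].
#' @export
apply_cohort_filters <- function(clinical,
                                 exclude_treated_norecurrence = FALSE,
                                 min_recurrence_months = 2,
                                 recurrence_window_months = 60) {
  validate_clinical(clinical)
  report <- tibble::tibble(sample_id = character(), rule = character(),
                           action = character())

  early <- clinical$event == 1 & clinical$time_months < min_recurrence_months
  if (any(early)) {
    report <- dplyr::bind_rows(report, tibble::tibble(
      sample_id = clinical$sample_id[early],
      rule = "early recurrence",
      action = sprintf("excluded (event at %.3g < %g months)",
                       clinical$time_months[early], min_recurrence_months)))
    clinical <- clinical[!early, , drop = FALSE]
  }

  late <- clinical$event == 1 & clinical$time_months > recurrence_window_months
  if (any(late)) {
    report <- dplyr::bind_rows(report, tibble::tibble(
      sample_id = clinical$sample_id[late],
      rule = "recurrence outside window",
      action = sprintf("recoded censored at %g months (event at %.3g)",
                       recurrence_window_months, clinical$time_months[late])))
    clinical$event[late] <- 0L
    clinical$time_months[late] <- recurrence_window_months
  }

  if (exclude_treated_norecurrence && "treatment_flag" %in% names(clinical)) {
    treated <- clinical$event == 0 &
      clinical$treatment_flag %in% c("chemo", "radio")
    if (any(treated)) {
      report <- dplyr::bind_rows(report, tibble::tibble(
        sample_id = clinical$sample_id[treated],
        rule = "treated norecurrence",
        action = "excluded (adjuvant/neoadjuvant therapy in event-free sample)"))
      clinical <- clinical[!treated, , drop = FALSE]
    }
  }

  attr(clinical, "exclusions") <- report
  clinical
}

#' Retrieve the exclusion report from a filtered clinical table
#'
#' @param clinical Output of [apply_cohort_filters()].
#' @return Tibble with columns `sample_id`, `rule`, `action` (empty if the
#'   table has not been filtered or nothing was removed).
#' @export
cohort_exclusions <- function(clinical) {
  attr(clinical, "exclusions") %||%
    tibble::tibble(sample_id = character(), rule = character(), action = character())
}
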