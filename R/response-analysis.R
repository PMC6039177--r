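# Lever-press response rates, acquisition baselines, exclusion filters and
# percent-of-baseline revaluation scores.
#
# Exclusion conventions:
#  * the acquisition criterion is the concrete press-count rule (at least
#    `min_presses` presses in one of the last two training sessions); the
#    equivalent ">0.25 presses/min over 60 min" phrasing is documented on
#    the argument;
#  * the 2-SD baseline-rate rule and the 3-SD percent-baseline rule compute
#    their statistics over the records passing the *earlier* filters, so
#    both filters are idempotent;
#  * boundary values are retained: exclusion requires strictly more than
#    `sd_cutoff` SDs from the mean.

#' Lever-press response rate
#'
#' @param session A [session()].
#' @param lever `"left"` (seeking, the default analysis lever) or
#'   `"right"`.
#' @return Presses per minute over the actual session duration.
#' @export
response_rate <- function(session, lever = c("left", "right")) {
  stopifnot(inherits(session, "lick_session"))
  lever <- match.arg(lever)
  if (session$duration <= 0) stop("session duration must be positive",
                                  call. = FALSE)
  kind <- paste0("lever_press_", lever)
  sum(session$events$kind == kind) / (session$duration / 60)
}

#' Baseline response rate from training sessions
#'
#' The mean response rate of the last two training sessions in
#' chronological order (all earlier sessions are ignored).
#'
#' @param training_sessions List of training [session()]s in chronological
#'   order (at least 2).
#' @param lever Passed to [response_rate()].
#' @return Baseline rate in presses per minute.
#' @export
baseline_rate <- function(training_sessions, lever = "left") {
  if (length(training_sessions) < 2) {
    stop("need at least 2 training sessions for a baseline", call. = FALSE)
  }
  last2 <- training_sessions[seq(length(training_sessions) - 1,
                                 length(training_sessions))]
  mean(vapply(last2, response_rate, numeric(1), lever = lever))
}

#' Percent of baseline responding
#'
#' `100 * rate_test / rate_baseline`; 100 means test responding equal to the
#' acquisition baseline, above 100 indicates upward revaluation.
#'
#' @param rate_test,rate_baseline Response rates in presses/min
#'   (vectorized).
#' @return Percent of baseline.
#' @export
percent_baseline <- function(rate_test, rate_baseline) {
  if (any(rate_baseline <= 0)) {
    stop("baseline rate must be positive (subject should have been excluded)",
         call. = FALSE)
  }
  100 * rate_test / rate_baseline
}

#' Acquisition filter and per-subject response records
#'
#' Builds one record per subject in the cohort design: baseline rate from
#' the last two training sessions, test rate from the non-rewarded test, and
#' inclusion flags. A subject is excluded with reason `"low_rate"` when
#' neither of its last two training sessions reaches `min_presses` presses
#' (the concrete form of the `min_rate` presses/min criterion over a 60-min
#' session), and with reason `"baseline_outlier"` when its baseline rate
#' lies strictly more than `sd_cutoff` SDs from the cohort mean (computed
#' over the rate-criterion survivors, so the filter is idempotent). The SD
#' rule is skipped with a warning when fewer than 3 subjects survive the
#' rate rule.
#'
#' @param cohort A [cohort()] whose subjects have `schedule_training`
#'   sessions and (optionally) a `test_nonrewarded` session.
#' @param min_rate Acquisition rate criterion in presses/min (documentation
#'   of the equivalent rule; the count rule below is operative).
#' @param min_presses Minimum presses in one of the last two training
#'   sessions.
#' @param sd_cutoff Baseline-rate outlier cutoff in SD units.
#' @param lever Analysis lever.
#' @return `data.frame` of response records: `subject_id`, `group`,
#'   `rate_baseline`, `rate_test`, `percent_baseline`, `included`,
#'   `exclusion_reason`.
#' @export
acquisition_filter <- function(cohort, min_rate = 0.25, min_presses = 15,
                               sd_cutoff = 2, lever = "left") {
  stopifnot(inherits(cohort, "lick_cohort"))
  design <- cohort$design
  kind <- paste0("lever_press_", lever)
  rec <- lapply(design$subject_id, function(sid) {
    train <- subject_sessions(cohort, sid, "schedule_training")
    test <- subject_sessions(cohort, sid, "test_nonrewarded")
    if (length(train) < 2) {
      return(data.frame(subject_id = sid, rate_baseline = NA_real_,
                        rate_test = NA_real_, best_presses = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    last2 <- train[seq(length(train) - 1, length(train))]
    presses <- vapply(last2, function(s) sum(s$events$kind == kind),
                      integer(1))
    data.frame(
      subject_id = sid,
      rate_baseline = baseline_rate(train, lever),
      rate_test = if (length(test)) response_rate(test[[1]], lever)
                  else NA_real_,
      best_presses = max(presses),
      stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rec)
  if ("group" %in% names(design)) {
    rec$group <- design$group[match(rec$subject_id, design$subject_id)]
  } else {
    rec$group <- "all"
  }

  rec$included <- TRUE
  rec$exclusion_reason <- NA_character_
  no_train <- is.na(rec$best_presses)
  rec$included[no_train] <- FALSE
  rec$exclusion_reason[no_train] <- "insufficient_training"
  low <- !no_train & rec$best_presses < min_presses
  rec$included[low] <- FALSE
  rec$exclusion_reason[low] <- "low_rate"

  survivors <- rec$included
  if (sum(survivors) >= 3) {
    mu <- mean(rec$rate_baseline[survivors])
    sdev <- stats::sd(rec$rate_baseline[survivors])
    if (sdev > 0) {
      z <- (rec$rate_baseline - mu) / sdev
      out <- survivors & abs(z) > sd_cutoff
      rec$included[out] <- FALSE
      rec$exclusion_reason[out] <- "baseline_outlier"
    }
  } else {
    warning("fewer than 3 qualifying subjects; SD exclusion rule skipped",
            call. = FALSE)
  }

  rec$percent_baseline <- NA_real_
  ok <- rec$included & !is.na(rec$rate_test) & rec$rate_baseline > 0
  rec$percent_baseline[ok] <- percent_baseline(rec$rate_test[ok],
                                               rec$rate_baseline[ok])
  rec[, c("subject_id", "group", "rate_baseline", "rate_test",
          "percent_baseline", "included", "exclusion_reason")]
}

#' Percent-of-baseline outlier filter
#'
#' Flags records whose percent-of-baseline score lies strictly more than
#' `sd_cutoff` SDs from their group mean. Statistics are computed over the
#' records that entered this filter included (ignoring exclusions this
#' filter itself produced on a previous pass), so applying the filter twice
#' changes nothing. With all values equal (zero SD) nothing is excluded.
#'
#' @param records Output of [acquisition_filter()].
#' @param sd_cutoff Cutoff in SD units (default 3).
#' @return `records` with updated `included` / `exclusion_reason`.
#' @export
percent_baseline_outlier_filter <- function(records, sd_cutoff = 3) {
  reason <- "percent_baseline_outlier"
  base <- (records$included |
             (!is.na(records$exclusion_reason) &
                records$exclusion_reason == reason)) &
    !is.na(records$percent_baseline)
  for (g in unique(records$group[base])) {
    idx <- base & records$group == g
    if (sum(idx) < 3) next
    mu <- mean(records$percent_baseline[idx])
    sdev <- stats::sd(records$percent_baseline[idx])
    if (is.na(sdev) || sdev == 0) next
    z <- abs((records$percent_baseline - mu) / sdev)
    flag <- idx & z > sd_cutoff
    records$included[flag] <- FALSE
    records$exclusion_reason[flag] <- reason
    unflag <- idx & z <= sd_cutoff & !records$included &
      !is.na(records$exclusion_reason) & records$exclusion_reason == reason
    records$included[unflag] <- TRUE
    records$exclusion_reason[unflag] <- NA_character_
  }
  records
}
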