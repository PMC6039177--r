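# Core data model: timestamped behavioral events, sessions, cohorts.
# All times are seconds from session start (0-based). Milliseconds appear
# only at presentation (figure-style summaries), never internally.

#' Recognized behavioral event codes
#'
#' The event vocabulary covers the observable streams of a two-lever operant
#' chamber with a contact lickometer and an optional light-delivery channel:
#' lever presses, sucrose deliveries, lick contacts (onset-only), lever
#' insertion/retraction, magazine entries and light on/off markers.
#'
#' @return Character vector of valid event kinds.
#' @export
event_kinds <- function() {
  c("lever_press_left", "lever_press_right", "sucrose_delivery",
    "lick_contact", "light_on", "light_off",
    "lever_insert_right", "lever_retract_right", "magazine_entry")
}

#' Recognized session phases
#'
#' Phases follow the standard incentive-learning protocol order: magazine
#' training, continuous reinforcement on the taking lever, chained schedule
#' training, non-contingent re-exposure, then brief non-rewarded and optional
#' rewarded tests.
#'
#' @return Character vector of phases in protocol order.
#' @export
session_phases <- function() {
  c("magazine", "crf", "schedule_training", "re_exposure",
    "test_nonrewarded", "test_rewarded")
}

#' Build an event table
#'
#' @param time Numeric vector of event times in seconds (non-negative).
#' @param kind Character vector of event codes (see [event_kinds()]).
#'   Unknown codes are allowed when `allow_unknown = TRUE` (used by the
#'   reader, which preserves rather than drops them).
#' @param payload Optional character vector of per-event JSON notes
#'   (`NA` for none).
#' @param allow_unknown Keep events whose kind is not in [event_kinds()]?
#' @return A `data.frame` with columns `time`, `kind`, `payload`, sorted
#'   stably by time.
#' @export
events_frame <- function(time = numeric(0), kind = character(0),
                         payload = NA_character_, allow_unknown = FALSE) {
  if (length(time) != length(kind)) {
    stop("`time` and `kind` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("event times must be finite and non-negative", call. = FALSE)
  }
  if (!allow_unknown && length(kind) && !all(kind %in% event_kinds())) {
    bad <- setdiff(unique(kind), event_kinds())
    stop("unknown event kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  payload <- rep_len(as.character(payload), length(time))
  ord <- order(time)  # stable sort, count-preserving
  data.frame(time = as.numeric(time)[ord], kind = as.character(kind)[ord],
             payload = payload[ord], stringsAsFactors = FALSE)
}

#' Construct a behavioral session
#'
#' A session is one subject's visit to the chamber: a sorted event table plus
#' design labels (phase, food-restriction schedule in hours, treatment).
#'
#' @param subject_id Subject identifier (string).
#' @param phase One of [session_phases()].
#' @param duration Session length in seconds; every event time must be
#'   `<= duration`. Non-rewarded tests default to 300 s.
#' @param events Event table from [events_frame()] (or compatible
#'   `data.frame`).
#' @param restriction_train,restriction_test Hours of food restriction during
#'   training and at re-exposure/test (e.g. 2 or 16).
#' @param treatment Opaque treatment label (e.g. `"control"`, `"attenuated"`,
#'   `"chr2"`, `"yoked"`).
#' @return An object of class `lick_session`.
#' @export
session <- function(subject_id, phase, duration,
                    events = events_frame(),
                    restriction_train = NA_real_, restriction_test = NA_real_,
                    treatment = "control") {
  phase <- match.arg(phase, session_phases())
  stopifnot(is.character(subject_id), length(subject_id) == 1,
            is.numeric(duration), length(duration) == 1, duration > 0)
  if (!is.data.frame(events) ||
      !all(c("time", "kind") %in% names(events))) {
    stop("`events` must be a data.frame with columns time and kind",
         call. = FALSE)
  }
  if (is.null(events$payload)) events$payload <- NA_character_
  ord <- order(events$time)
  events <- events[ord, c("time", "kind", "payload"), drop = FALSE]
  rownames(events) <- NULL
  if (nrow(events) && any(events$time < 0)) {
    stop("negative event time in session ", subject_id, call. = FALSE)
  }
  if (nrow(events) && any(events$time > duration)) {
    stop("event beyond session duration in session ", subject_id,
         call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, phase = phase, duration = duration,
         restriction_train = restriction_train,
         restriction_test = restriction_test,
         treatment = treatment, events = events),
    class = "lick_session")
}

#' @export
print.lick_session <- function(x, ...) {
  cat(sprintf("<lick_session> subject %s, phase %s, %.0f s, %d events\n",
              x$subject_id, x$phase, x$duration, nrow(x$events)))
  tab <- table(x$events$kind)
  if (length(tab)) {
    cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

# Extract times of a given event kind from a session.
event_times <- function(session, kind) {
  session$events$time[session$events$kind == kind]
}

#' Construct a cohort
#'
#' @param sessions List of [session()] objects.
#' @param design `data.frame` mapping `subject_id` to
#'   `restriction_train`, `restriction_test`, `treatment` and a `group`
#'   label such as `"2-16"`.
#' @return An object of class `lick_cohort`.
#' @export
cohort <- function(sessions, design) {
  stopifnot(is.list(sessions),
            all(vapply(sessions, inherits, logical(1), "lick_session")),
            is.data.frame(design), "subject_id" %in% names(design))
  structure(list(sessions = sessions, design = design),
            class = "lick_cohort")
}

#' @export
print.lick_cohort <- function(x, ...) {
  cat(sprintf("<lick_cohort> %d sessions, %d subjects, groups: %s\n",
              length(x$sessions), nrow(x$design),
              paste(unique(x$design$group), collapse = ", ")))
  invisible(x)
}

# Sessions belonging to one subject, in list order (assumed chronological).
subject_sessions <- function(cohort, subject_id, phase = NULL) {
  keep <- vapply(cohort$sessions, function(s) {
    s$subject_id == subject_id && (is.null(phase) || s$phase %in% phase)
  }, logical(1))
  cohort$sessions[keep]
}

#' Validate a cohort against the data-model invariants
#'
#' Checks, per session: events sorted by time, no negative times, no event
#' beyond the session duration, known event kinds; per subject: membership in
#' the design table and protocol-ordered phases (training phases before
#' re-exposure before tests, following list order as chronology).
#'
#' Violations are data, not exceptions: a well-formed cohort returns a
#' zero-row table.
#'
#' @param cohort A [cohort()].
#' @return `data.frame` with columns `subject_id`, `session`, `rule`,
#'   `detail`; zero rows iff all invariants hold.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "lick_cohort"))
  v <- list()
  add <- function(subject, sess, rule, detail) {
    v[[length(v) + 1]] <<- data.frame(
      subject_id = subject, session = sess, rule = rule, detail = detail,
      stringsAsFactors = FALSE)
  }
  rank <- stats::setNames(seq_along(session_phases()), session_phases())
  last_rank <- list()
  for (i in seq_along(cohort$sessions)) {
    s <- cohort$sessions[[i]]
    sid <- s$subject_id
    if (!sid %in% cohort$design$subject_id) {
      add(sid, i, "design_membership", "subject missing from design table")
    }
    ev <- s$events
    if (nrow(ev)) {
      if (is.unsorted(ev$time)) {
        add(sid, i, "events_sorted", "event times not non-decreasing")
      }
      if (any(ev$time < 0)) add(sid, i, "time_nonnegative", "negative time")
      if (any(ev$time > s$duration)) {
        add(sid, i, "time_within_duration", "event beyond session duration")
      }
      unknown <- setdiff(unique(ev$kind), event_kinds())
      if (length(unknown)) {
        add(sid, i, "known_kind", paste(unknown, collapse = ", "))
      }
    }
    r <- rank[[s$phase]]
    prev <- last_rank[[sid]]
    if (!is.null(prev) && r < prev) {
      add(sid, i, "phase_order",
          sprintf("phase %s after a later-protocol phase", s$phase))
    }
    last_rank[[sid]] <- max(r, if (is.null(prev)) r else prev)
  }
  if (!length(v)) {
    return(data.frame(subject_id = character(0), session = integer(0),
                      rule = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}
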