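# Operant schedule simulation: random-ratio requirement sampling,
# random-time delivery processes, the chained RR -> FR1 state machine, and
# the closed-loop lick-triggered light controller with yoked copies.
#
# Randomness comes from R's global RNG stream: callers seed with set.seed()
# (or via a generator config) for reproducibility.

#' Schedule configuration
#'
#' @param kind `"RR"` (random ratio: each press reinforced with probability
#'   1/parameter, so required presses per reinforcer are geometric with mean
#'   `parameter`), `"RT"` (random time: non-contingent deliveries as a
#'   Poisson process with mean interval `parameter` seconds), `"FR"` (fixed
#'   ratio), or `"CRF"` (continuous reinforcement, equivalent to FR1).
#' @param parameter RR mean ratio, RT mean interval (s), or FR count; must
#'   be positive (integer for FR, >= 1 for RR).
#' @return An object of class `schedule_config`.
#' @export
schedule_config <- function(kind = c("RR", "RT", "FR", "CRF"), parameter = 1) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(parameter), length(parameter) == 1,
            is.finite(parameter), parameter > 0)
  if (kind == "FR" && parameter != round(parameter)) {
    stop("FR parameter must be a whole number", call. = FALSE)
  }
  if (kind == "RR" && parameter < 1) {
    stop("RR ratio must be >= 1", call. = FALSE)
  }
  if (kind == "CRF") parameter <- 1
  structure(list(kind = kind, parameter = parameter),
            class = "schedule_config")
}

#' Draw random-ratio press requirements
#'
#' Implements the per-press Bernoulli convention: each press is reinforced
#' with probability `1/ratio`, so the number of presses required for the
#' next reinforcer is geometric on 1, 2, ... with mean equal to the ratio.
#' RR1 degenerates to a requirement of exactly 1.
#'
#' @param config A `schedule_config` with `kind = "RR"`.
#' @param n Number of requirements to draw.
#' @return Integer vector of press requirements.
#' @export
rr_requirement <- function(config, n = 1) {
  stopifnot(inherits(config, "schedule_config"))
  if (config$kind != "RR") stop("config is not an RR schedule", call. = FALSE)
  stats::rgeom(n, prob = 1 / config$parameter) + 1L
}

#' Simulate random-time delivery times
#'
#' Deliveries form a homogeneous Poisson process on `[0, duration]`:
#' inter-delivery intervals are exponential with mean `config$parameter`
#' seconds, truncated at the session end. An RT120 schedule over 3600 s
#' therefore yields 30 deliveries on average.
#'
#' @param config A `schedule_config` with `kind = "RT"`.
#' @param duration Session length in seconds (0 gives an empty vector).
#' @return Sorted numeric vector of delivery times.
#' @export
rt_delivery_times <- function(config, duration) {
  stopifnot(inherits(config, "schedule_config"))
  if (config$kind != "RT") stop("config is not an RT schedule", call. = FALSE)
  if (!is.numeric(duration) || length(duration) != 1 || duration < 0) {
    stop("duration must be a non-negative number", call. = FALSE)
  }
  if (duration == 0) return(numeric(0))
  mu <- config$parameter
  expected <- duration / mu
  n_chunk <- max(16L, ceiling(expected + 6 * sqrt(expected) + 4))
  times <- cumsum(stats::rexp(n_chunk, rate = 1 / mu))
  while (times[length(times)] <= duration) {
    times <- c(times, times[length(times)] +
                 cumsum(stats::rexp(n_chunk, rate = 1 / mu)))
  }
  times[times <= duration]
}

#' Replay a press stream through the chained RR -> FR1 state machine
#'
#' The session begins with the left (seeking) lever available and the right
#' (taking) lever retracted. Left presses count toward the current RR
#' requirement only while the right lever is retracted; completing the
#' requirement inserts the right lever; the next right press delivers
#' sucrose, retracts the right lever, and a fresh requirement is drawn.
#' Presses on an uninserted right lever (and left presses while the right
#' lever is inserted) are recorded but have no effect. The session stops
#' reinforcing at `cap` deliveries or at `duration`, whichever comes first.
#'
#' With `left_schedule = NULL` or kind `"CRF"` the right lever is inserted
#' from t = 0 and never retracts: every right press up to the cap is
#' reinforced (continuous-reinforcement sessions).
#'
#' @param left_schedule `schedule_config` of kind `"RR"` or `"FR"` for the
#'   seeking lever, or `NULL`/`"CRF"` for right-lever-only sessions.
#' @param press_stream `data.frame` with columns `time` (sorted, seconds)
#'   and `lever` (`"left"` or `"right"`).
#' @param duration Session length in seconds; presses beyond it are ignored.
#' @param cap Maximum number of deliveries (default unlimited).
#' @param requirements Optional pre-drawn integer vector of RR/FR
#'   requirements consumed in order (used by the synthetic generator to keep
#'   its own bookkeeping aligned with the engine); when exhausted or `NULL`,
#'   requirements are drawn from `left_schedule`.
#' @param right_schedule Taking-lever schedule; only FR1 is supported.
#' @return Event table (see [events_frame()]) containing the presses and the
#'   resulting `lever_insert_right` / `lever_retract_right` /
#'   `sucrose_delivery` events.
#' @export
run_chain_session <- function(left_schedule,
                              press_stream, duration, cap = Inf,
                              requirements = NULL,
                              right_schedule = schedule_config("FR", 1)) {
  stopifnot(is.data.frame(press_stream),
            all(c("time", "lever") %in% names(press_stream)))
  if (!(right_schedule$kind %in% c("FR", "CRF")) ||
      right_schedule$parameter != 1) {
    stop("right lever must be on FR1", call. = FALSE)
  }
  if (nrow(press_stream) && is.unsorted(press_stream$time)) {
    stop("press_stream must be sorted by time", call. = FALSE)
  }
  crf_mode <- is.null(left_schedule) || left_schedule$kind == "CRF"
  if (!crf_mode && !(left_schedule$kind %in% c("RR", "FR"))) {
    stop("left lever schedule must be RR, FR or CRF/NULL", call. = FALSE)
  }

  ev_time <- numeric(0)
  ev_kind <- character(0)
  add <- function(t, k) {
    ev_time[length(ev_time) + 1L] <<- t
    ev_kind[length(ev_kind) + 1L] <<- k
  }

  req_i <- 0L
  next_req <- function() {
    req_i <<- req_i + 1L
    if (!is.null(requirements) && req_i <= length(requirements)) {
      return(as.integer(requirements[req_i]))
    }
    if (left_schedule$kind == "FR") as.integer(left_schedule$parameter)
    else rr_requirement(left_schedule)
  }

  right_in <- crf_mode
  if (crf_mode) add(0, "lever_insert_right")
  count <- 0L
  req <- if (crf_mode) NA_integer_ else next_req()
  deliveries <- 0L

  keep <- press_stream$time <= duration
  times <- press_stream$time[keep]
  levers <- press_stream$lever[keep]
  for (i in seq_along(times)) {
    t <- times[i]
    if (levers[i] == "left") {
      add(t, "lever_press_left")
      if (!crf_mode && !right_in) {
        count <- count + 1L
        if (count >= req) {
          right_in <- TRUE
          add(t, "lever_insert_right")
        }
      }
    } else {
      add(t, "lever_press_right")
      if (right_in && deliveries < cap) {
        deliveries <- deliveries + 1L
        add(t, "sucrose_delivery")
        if (!crf_mode) {
          right_in <- FALSE
          add(t, "lever_retract_right")
          count <- 0L
          req <- next_req()
        }
      }
    }
  }
  events_frame(ev_time, ev_kind)
}

#' Construct a light-stimulation train
#'
#' Default parameters follow the consumption-locked inhibition protocol:
#' 20 Hz, 5 ms pulses for 5 s (100 pulses per train).
#'
#' @param onset Train onset (s from session start).
#' @param frequency Pulse rate in Hz.
#' @param pulse_width Pulse width in seconds.
#' @param duration Train length in seconds.
#' @return Object of class `stim_train` with derived `pulse_onsets`
#'   (`floor(frequency * duration)` pulses, all within
#'   `[onset, onset + duration]`).
#' @export
stim_train <- function(onset, frequency = 20, pulse_width = 0.005,
                       duration = 5) {
  stopifnot(is.numeric(onset), onset >= 0, frequency > 0, pulse_width > 0,
            duration > 0, pulse_width <= 1 / frequency)
  n <- floor(frequency * duration)
  structure(
    list(onset = onset, frequency = frequency, pulse_width = pulse_width,
         duration = duration,
         pulse_onsets = onset + (seq_len(n) - 1) / frequency),
    class = "stim_train")
}

#' Closed-loop lick-triggered stimulation trains
#'
#' For each delivery, the first lick at or after the delivery and before the
#' next one triggers exactly one train, with onset = lick time + trigger
#' latency (hardware delay ~10-20 ms). At most one train per delivery; a
#' delivery with no qualifying lick produces no train; trains never
#' re-trigger while one is active -- if the next delivery falls inside an
#' active train, its trigger window starts at the train's end.
#'
#' @param deliveries Sorted numeric vector of delivery times (s).
#' @param licks Sorted numeric vector of (debounced) lick onset times (s).
#' @param latency Trigger latency in seconds: a scalar, or a length-2 range
#'   from which each train's latency is drawn uniformly (default
#'   `c(0.010, 0.020)`). Must lie in `[0, 1)`.
#' @param frequency,pulse_width,train_duration Train parameters, see
#'   [stim_train()].
#' @return List of [stim_train()] objects.
#' @export
closed_loop_trains <- function(deliveries, licks, latency = c(0.010, 0.020),
                               frequency = 20, pulse_width = 0.005,
                               train_duration = 5) {
  if (any(latency < 0) || any(latency >= 1)) {
    stop("trigger latency must lie in [0, 1) s", call. = FALSE)
  }
  if (length(latency) > 2) stop("latency must be scalar or a range",
                                call. = FALSE)
  if (is.unsorted(deliveries) || is.unsorted(licks)) {
    stop("deliveries and licks must be sorted", call. = FALSE)
  }
  trains <- list()
  active_end <- -Inf
  n_d <- length(deliveries)
  for (i in seq_len(n_d)) {
    win_start <- max(deliveries[i], active_end)
    win_end <- if (i < n_d) deliveries[i + 1] else Inf
    k <- findInterval(win_start, licks, left.open = TRUE) + 1L
    if (k > length(licks) || licks[k] >= win_end) next
    lat <- if (length(latency) == 2) {
      stats::runif(1, latency[1], latency[2])
    } else latency
    tr <- stim_train(licks[k] + lat, frequency, pulse_width, train_duration)
    active_end <- tr$onset + tr$duration
    trains[[length(trains) + 1L]] <- tr
  }
  trains
}

#' Yoke stimulation trains to another subject's session
#'
#' Returns trains with onsets and parameters copied exactly from the source;
#' the target session's behavior is never consulted (the defining property
#' of a yoked control). Trains whose onset falls beyond the target session's
#' duration are dropped with a warning.
#'
#' @param source List of [stim_train()] objects (the closed-loop partner's
#'   trains).
#' @param target_session The yoked subject's [session()].
#' @return List of [stim_train()] objects.
#' @export
yoke_trains <- function(source, target_session) {
  stopifnot(inherits(target_session, "lick_session"))
  onsets <- vapply(source, `[[`, numeric(1), "onset")
  drop <- onsets > target_session$duration
  if (any(drop)) {
    warning(sum(drop), " train(s) beyond target session duration dropped",
            call. = FALSE)
  }
  lapply(source[!drop], function(tr) {
    stim_train(tr$onset, tr$frequency, tr$pulse_width, tr$duration)
  })
}

# Represent trains as light_on/light_off rows for embedding in a session.
trains_to_events <- function(trains) {
  if (!length(trains)) return(events_frame())
  on <- vapply(trains, `[[`, numeric(1), "onset")
  dur <- vapply(trains, `[[`, numeric(1), "duration")
  events_frame(c(on, on + dur),
               c(rep("light_on", length(on)), rep("light_off", length(on))))
}
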