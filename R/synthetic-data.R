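# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: state-dependent lick microstructure (motivational state
# scales licks per burst and shortens post-delivery latency), lever-press
# Poisson processes under the chained RR -> FR1 schedule, and the
# incentive-learning contract -- the updated (test-state) value drives
# seeking at test only if value updating occurred, i.e. if updating is
# intact AND sucrose was experienced at re-exposure. Palatability
# (lick-train law) depends only on the current state, never on the
# updating switch: that dissociation is the core pattern the pipeline must
# recover.

#' Map hours of food restriction to a motivational-state multiplier
#'
#' Linear interpolation anchored at 2 h -> 1.0 and 16 h -> `s_hi`; the
#' state multiplies lick and press parameters through power links.
#'
#' @param hours Hours of daily food restriction.
#' @param s_hi State multiplier at 16 h restriction.
#' @return Positive state multiplier.
#' @export
restriction_state <- function(hours, s_hi = 1.6) {
  stopifnot(all(hours >= 0), s_hi > 0)
  1 + (s_hi - 1) * (hours - 2) / 14
}

#' Generative configuration for a synthetic group
#'
#' Defaults encode one group of a mouse incentive-learning experiment:
#' 10 subjects; two 60-min chained RR4 -> FR1 training sessions with a
#' seeking rate of 0.58 presses/min in the training state; a 60-min RT120
#' re-exposure (mean one delivery per 2 min); and a 5-min non-rewarded
#' test. Lick defaults are typical for C57BL/6J mice: ~6 licks per
#' consummatory burst at the 2-h-restriction state, 130 ms within-burst
#' inter-lick interval (7-8 Hz licking), 4 s mean latency from delivery to
#' the first lick, and a sparse 1 lick/min anticipatory background; all
#' licks respect the 10 ms lickometer debounce floor.
#'
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param n_subjects Subjects in the group.
#' @param restriction_train_hr,restriction_test_hr Hours of food
#'   restriction during training and at re-exposure/test (2 or 16 in the
#'   standard designs).
#' @param s_hi State multiplier at 16 h restriction (see
#'   [restriction_state()]).
#' @param press_rate_base Seeking-lever press rate (presses/min) at state 1.
#' @param value_update_intact `FALSE` emulates a manipulation that blocks
#'   experience-based value updating while leaving palatability intact.
#' @param sucrose_at_reexposure `FALSE` gives a context-only re-exposure
#'   (no deliveries), which also prevents updating.
#' @param burst_lick_mean Mean licks per consummatory burst at state 1
#'   (minimum 2; shifted-Poisson draw).
#' @param within_burst_ili_mean Mean within-burst inter-lick interval (s).
#' @param ili_shape Gamma shape of within-burst intervals.
#' @param latency_mean Mean delivery-to-first-lick latency (s) at state 1;
#'   divided by the state multiplier (higher state licks sooner).
#' @param latency_sdlog Log-scale SD of the lognormal latency.
#' @param anticipatory_rate Background (non-consummatory) lick rate,
#'   licks/min.
#' @param press_exponent,lick_exponent Exponents of the multiplicative
#'   power links `f(state) = state^press_exponent` (seeking rate) and
#'   `g(state) = state^lick_exponent` (lick parameters).
#' @param rr_ratio Random-ratio requirement of the seeking lever during
#'   training.
#' @param rt_interval Mean delivery interval of the re-exposure RT schedule
#'   (s).
#' @param training_duration,reexposure_duration,test_duration Session
#'   lengths (s).
#' @param n_training_sessions Training sessions per subject (the last two
#'   define the baseline).
#' @param treatment Treatment label copied into sessions and design (e.g.
#'   `"control"`, `"attenuated"`, `"chr2"`).
#' @param closed_loop Attach closed-loop lick-triggered light trains to the
#'   re-exposure session?
#' @param right_press_latency_mean Mean taking-lever latency after
#'   insertion (s, lognormal).
#' @param debounce Lickometer floor (s).
#' @return Object of class `generative_config`.
#' @export
generative_config <- function(seed = NULL, n_subjects = 10,
                              restriction_train_hr = 2,
                              restriction_test_hr = 2,
                              s_hi = 1.6,
                              press_rate_base = 0.58,
                              value_update_intact = TRUE,
                              sucrose_at_reexposure = TRUE,
                              burst_lick_mean = 6,
                              within_burst_ili_mean = 0.13,
                              ili_shape = 4,
                              latency_mean = 4,
                              latency_sdlog = 0.5,
                              anticipatory_rate = 1,
                              press_exponent = 1,
                              lick_exponent = 1,
                              rr_ratio = 4,
                              rt_interval = 120,
                              training_duration = 3600,
                              reexposure_duration = 3600,
                              test_duration = 300,
                              n_training_sessions = 2,
                              treatment = "control",
                              closed_loop = FALSE,
                              right_press_latency_mean = 1.5,
                              debounce = 0.010) {
  cfg <- as.list(environment())
  rates <- c(press_rate_base, burst_lick_mean, within_burst_ili_mean,
             latency_mean, anticipatory_rate, rr_ratio, rt_interval,
             s_hi, ili_shape, right_press_latency_mean)
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("all generative rates and means must be positive", call. = FALSE)
  }
  cfg$state_train <- restriction_state(restriction_train_hr, s_hi)
  cfg$state_test <- restriction_state(restriction_test_hr, s_hi)
  structure(cfg, class = "generative_config")
}

f_press <- function(config, state) state^config$press_exponent
g_lick <- function(config, state) state^config$lick_exponent

# The remembered value-state driving seeking at test: the test state if
# updating occurred (intact AND sucrose experienced), else the training
# state.
effective_state <- function(config) {
  if (config$value_update_intact && config$sucrose_at_reexposure) {
    config$state_test
  } else {
    config$state_train
  }
}

# Homogeneous Poisson event times on [0, duration] at `rate` per second.
poisson_times <- function(rate, duration) {
  if (rate <= 0 || duration <= 0) return(numeric(0))
  expected <- rate * duration
  n_chunk <- max(16L, ceiling(expected + 6 * sqrt(expected) + 4))
  t <- cumsum(stats::rexp(n_chunk, rate = rate))
  while (t[length(t)] <= duration) {
    t <- c(t, t[length(t)] + cumsum(stats::rexp(n_chunk, rate = rate)))
  }
  t[t <= duration]
}

#' Generate a seeking-lever press process
#'
#' Left presses are a homogeneous Poisson process with rate
#' `press_rate_base * f(state)` presses/min, where `f` is the power link of
#' the config. The `state` passed in should be the *effective* state: the
#' test-session motivational value is the updated one only when updating
#' occurred (see [generative_config()]).
#'
#' @param config A [generative_config()].
#' @param state Motivational-state multiplier.
#' @param duration Session length (s).
#' @return Sorted numeric vector of left-press times.
#' @export
generate_press_stream <- function(config, state, duration) {
  stopifnot(inherits(config, "generative_config"), state > 0)
  poisson_times(config$press_rate_base * f_press(config, state) / 60,
                duration)
}

#' Generate a lick train around scheduled deliveries
#'
#' Per delivery: a lognormal latency with mean `latency_mean / g(state)`,
#' then a consummatory burst whose lick count is a shifted Poisson with
#' mean `burst_lick_mean * g(state)` (minimum 2) and whose inter-lick
#' intervals are gamma with mean `within_burst_ili_mean`, floored at the
#' debounce window. Sparse anticipatory licks form a Poisson background.
#' Bursts overlapping the next delivery are truncated there. Palatability
#' parameters depend only on the current state, never on the
#' value-updating switch.
#'
#' @param config A [generative_config()].
#' @param state Motivational-state multiplier at re-exposure.
#' @param deliveries Sorted delivery times (s).
#' @param duration Session length (s).
#' @return Sorted, debounced lick onset times.
#' @export
generate_lick_train <- function(config, state, deliveries, duration) {
  stopifnot(inherits(config, "generative_config"), state > 0)
  if (is.unsorted(deliveries)) stop("deliveries must be sorted",
                                    call. = FALSE)
  g <- g_lick(config, state)
  licks <- poisson_times(config$anticipatory_rate / 60, duration)
  mlog <- log(config$latency_mean / g) - config$latency_sdlog^2 / 2
  n_d <- length(deliveries)
  burst_lists <- vector("list", n_d)
  for (i in seq_len(n_d)) {
    upper <- if (i < n_d) deliveries[i + 1] else duration
    lat <- stats::rlnorm(1, meanlog = mlog, sdlog = config$latency_sdlog)
    start <- deliveries[i] + lat
    if (start >= upper) next
    n_licks <- 2L + stats::rpois(1, max(config$burst_lick_mean * g - 2, 1e-9))
    ilis <- pmax(config$debounce,
                 stats::rgamma(n_licks - 1L, shape = config$ili_shape,
                               rate = config$ili_shape /
                                 config$within_burst_ili_mean))
    tt <- start + c(0, cumsum(ilis))
    burst_lists[[i]] <- tt[tt < upper]
  }
  all_licks <- sort(c(licks, unlist(burst_lists)))
  debounce_licks(all_licks, config$debounce)
}

# One chained-schedule training session: simulate the left-press Poisson
# process, schedule taking-lever presses after each completed requirement,
# and replay the combined stream through the engine with the same
# pre-drawn requirements so generator and engine agree on the chain state.
generate_training_session <- function(config, subject_id) {
  dur <- config$training_duration
  lefts <- generate_press_stream(config, config$state_train, dur)
  sched <- schedule_config("RR", config$rr_ratio)
  rmlog <- log(config$right_press_latency_mean) - 0.4^2 / 2
  reqs <- integer(0)
  rights <- numeric(0)
  count <- 0L
  blocked_until <- -Inf
  req <- rr_requirement(sched)
  reqs <- c(reqs, req)
  for (t in lefts) {
    if (t < blocked_until) next
    count <- count + 1L
    if (count >= req) {
      tr <- t + stats::rlnorm(1, meanlog = rmlog, sdlog = 0.4)
      if (tr <= dur) {
        rights <- c(rights, tr)
        count <- 0L
        req <- rr_requirement(sched)
        reqs <- c(reqs, req)
        blocked_until <- tr
      } else {
        blocked_until <- Inf
      }
    }
  }
  stream <- data.frame(
    time = c(lefts, rights),
    lever = c(rep("left", length(lefts)), rep("right", length(rights))),
    stringsAsFactors = FALSE)
  stream <- stream[order(stream$time), ]
  ev <- run_chain_session(sched, stream, dur, requirements = reqs)
  session(subject_id, "schedule_training", dur, ev,
          restriction_train = config$restriction_train_hr,
          restriction_test = config$restriction_test_hr,
          treatment = config$treatment)
}

generate_reexposure_session <- function(config, subject_id) {
  dur <- config$reexposure_duration
  deliveries <- if (config$sucrose_at_reexposure) {
    rt_delivery_times(schedule_config("RT", config$rt_interval), dur)
  } else numeric(0)
  licks <- generate_lick_train(config, config$state_test, deliveries, dur)
  ev <- events_frame(
    c(deliveries, licks),
    c(rep("sucrose_delivery", length(deliveries)),
      rep("lick_contact", length(licks))))
  if (config$closed_loop && length(deliveries)) {
    trains <- closed_loop_trains(deliveries, licks)
    tev <- trains_to_events(trains)
    tev$time <- pmin(tev$time, dur)  # a train may outlast the session
    ev <- events_frame(c(ev$time, tev$time), c(ev$kind, tev$kind))
  }
  session(subject_id, "re_exposure", dur, ev,
          restriction_train = config$restriction_train_hr,
          restriction_test = config$restriction_test_hr,
          treatment = config$treatment)
}

generate_test_session <- function(config, subject_id) {
  dur <- config$test_duration
  presses <- generate_press_stream(config, effective_state(config), dur)
  ev <- events_frame(presses, rep("lever_press_left", length(presses)))
  session(subject_id, "test_nonrewarded", dur, ev,
          restriction_train = config$restriction_train_hr,
          restriction_test = config$restriction_test_hr,
          treatment = config$treatment)
}

#' Generate a synthetic group cohort with ground truth
#'
#' Per subject: `n_training_sessions` chained-schedule training sessions,
#' one non-contingent re-exposure session (RT deliveries with state-scaled
#' licking; optionally closed-loop light trains), and a brief non-rewarded
#' test whose seeking rate reflects the effective (remembered) value state.
#' Deterministic under `config$seed`. The recorded ground truth is never
#' consumed by the analysis modules.
#'
#' @param config A [generative_config()].
#' @param subject_prefix Prefix for generated subject ids (keeps ids unique
#'   when merging groups).
#' @return List with elements `cohort` (a [cohort()]) and `ground_truth`
#'   (`data.frame` of per-subject states and the expected
#'   percent-of-baseline ratio).
#' @export
generate_cohort <- function(config, subject_prefix = NULL) {
  stopifnot(inherits(config, "generative_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  group <- sprintf("%g-%g", config$restriction_train_hr,
                   config$restriction_test_hr)
  if (is.null(subject_prefix)) {
    subject_prefix <- sprintf("%s_%s", gsub("-", "to", group),
                              config$treatment)
  }
  ids <- sprintf("%s_%02d", subject_prefix, seq_len(config$n_subjects))
  sessions <- list()
  for (sid in ids) {
    for (k in seq_len(config$n_training_sessions)) {
      sessions[[length(sessions) + 1L]] <-
        generate_training_session(config, sid)
    }
    sessions[[length(sessions) + 1L]] <-
      generate_reexposure_session(config, sid)
    sessions[[length(sessions) + 1L]] <- generate_test_session(config, sid)
  }
  design <- data.frame(
    subject_id = ids,
    restriction_train = config$restriction_train_hr,
    restriction_test = config$restriction_test_hr,
    treatment = config$treatment, group = group,
    stringsAsFactors = FALSE)
  s_eff <- effective_state(config)
  truth <- data.frame(
    subject_id = ids, group = group,
    state_train = config$state_train, state_test = config$state_test,
    state_effective = s_eff,
    value_update_intact = config$value_update_intact,
    sucrose_at_reexposure = config$sucrose_at_reexposure,
    expected_percent_baseline =
      100 * f_press(config, s_eff) / f_press(config, config$state_train),
    burst_lick_mean_effective =
      config$burst_lick_mean * g_lick(config, config$state_test),
    stringsAsFactors = FALSE)
  list(cohort = cohort(sessions, design), ground_truth = truth)
}

#' Merge group cohorts into one experiment cohort
#'
#' @param ... [cohort()] objects (e.g. one per group).
#' @return A single [cohort()] with concatenated sessions and design rows.
#' @export
merge_cohorts <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "lick_cohort")))
  ids <- unlist(lapply(parts, function(cc) cc$design$subject_id))
  if (anyDuplicated(ids)) {
    stop("duplicated subject ids across merged cohorts", call. = FALSE)
  }
  cohort(do.call(c, lapply(parts, `[[`, "sessions")),
         do.call(rbind, lapply(parts, `[[`, "design")))
}
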