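# Independent oracles and fixture builders shared across the suite.

# Exhaustive burst oracle: test every contiguous run of licks for the burst
# predicate (all internal ILIs strictly under threshold, >= min_licks) and
# maximality (the neighboring licks, if any, are >= threshold away).
# Quadratic on purpose: it shares no code with segment_bursts().
brute_force_bursts <- function(times, ili_threshold = 1.0, min_licks = 2) {
  n <- length(times)
  rows <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i + 1 < min_licks) next
      run <- times[i:j]
      if (any(diff(run) >= ili_threshold)) next
      left_max <- i == 1 || (times[i] - times[i - 1]) >= ili_threshold
      right_max <- j == n || (times[j + 1] - times[j]) >= ili_threshold
      if (left_max && right_max) {
        rows[[length(rows) + 1]] <- data.frame(
          start = run[1], end = run[j - i + 1], n_licks = j - i + 1L)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_licks = integer(0)))
  }
  do.call(rbind, rows)
}

# Random lick train with a mixture of short (within-burst scale) and long
# gaps, including occasional gaps right at the threshold boundary.
random_lick_train <- function(n = 30, ili_threshold = 1.0) {
  gaps <- sample(c(stats::rexp(n, 1 / 0.15),
                   stats::rexp(n, 1 / 3),
                   rep(ili_threshold, n)),
                 n, replace = TRUE)
  cumsum(c(stats::rexp(1, 1), gaps[-1]))
}

# Split-plot sums-of-squares oracle for one between factor, one within
# factor, balanced complete data. Computed directly from cell/marginal
# means, independent of aov().
split_plot_oracle <- function(data, outcome, between, within, subject) {
  y <- data[[outcome]]
  g <- factor(data[[between]])
  w <- factor(data[[within]])
  s <- factor(data[[subject]])
  n_w <- nlevels(w)
  grand <- mean(y)
  subj_mean <- tapply(y, s, mean)
  subj_group <- tapply(as.character(g), s, `[`, 1)
  group_mean <- tapply(y, g, mean)
  block_mean <- tapply(y, w, mean)
  cell_mean <- tapply(y, list(g, w), mean)
  n_per_group <- table(subj_group)[levels(g)]
  n_subj <- nlevels(s)

  ss_g <- n_w * sum(n_per_group * (group_mean - grand)^2)
  ss_subj <- n_w * sum((subj_mean - group_mean[subj_group])^2)
  ss_w <- n_subj * sum((block_mean - grand)^2)
  ss_gw <- 0
  for (gi in levels(g)) {
    for (wi in levels(w)) {
      dev <- cell_mean[gi, wi] - group_mean[gi] - block_mean[wi] + grand
      ss_gw <- ss_gw + n_per_group[[gi]] * dev^2
    }
  }
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_g - ss_subj - ss_w - ss_gw

  df_g <- nlevels(g) - 1
  df_subj <- n_subj - nlevels(g)
  df_w <- n_w - 1
  df_gw <- df_g * df_w
  df_err <- df_subj * df_w

  data.frame(
    effect = c(between, within, paste0(between, ":", within)),
    df_num = c(df_g, df_w, df_gw),
    df_den = c(df_subj, df_err, df_err),
    F = c((ss_g / df_g) / (ss_subj / df_subj),
          (ss_w / df_w) / (ss_err / df_err),
          (ss_gw / df_gw) / (ss_err / df_err)),
    stringsAsFactors = FALSE)
}

# Minimal hand-built session: left presses at given times.
press_session <- function(times, duration = 3600, subject_id = "s1",
                          phase = "schedule_training", lever = "left") {
  session(subject_id, phase, duration,
          events_frame(times, rep(paste0("lever_press_", lever),
                                  length(times))))
}

# Session with given lick and delivery times.
lick_session_fixture <- function(licks, deliveries = numeric(0),
                                 duration = 3600, subject_id = "s1") {
  session(subject_id, "re_exposure", duration,
          events_frame(
            c(licks, deliveries),
            c(rep("lick_contact", length(licks)),
              rep("sucrose_delivery", length(deliveries)))))
}

# Small training+test cohort for the response-analysis filters: one row per
# subject giving press counts on the two baseline days and the test count.
filter_cohort <- function(counts_day1, counts_day2, counts_test,
                          duration_train = 3600, duration_test = 300) {
  n <- length(counts_day1)
  ids <- sprintf("m%02d", seq_len(n))
  sessions <- list()
  spread <- function(k, dur) if (k > 0) seq(1, dur - 1, length.out = k)
                             else numeric(0)
  for (i in seq_len(n)) {
    sessions[[length(sessions) + 1]] <-
      press_session(spread(counts_day1[i], duration_train),
                    duration_train, ids[i])
    sessions[[length(sessions) + 1]] <-
      press_session(spread(counts_day2[i], duration_train),
                    duration_train, ids[i])
    sessions[[length(sessions) + 1]] <-
      press_session(spread(counts_test[i], duration_test), duration_test,
                    ids[i], phase = "test_nonrewarded")
  }
  cohort(sessions,
         data.frame(subject_id = ids, restriction_train = 2,
                    restriction_test = 2, treatment = "control",
                    group = "2-2", stringsAsFactors = FALSE))
}
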