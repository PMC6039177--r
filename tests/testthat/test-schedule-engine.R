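# Operant schedule engine: RR sampling, RT processes, the chain state
# machine, closed-loop stimulation and yoked copies.

test_that("RR1 requirement is always exactly one press", {
  set.seed(1)
  expect_true(all(rr_requirement(schedule_config("RR", 1), 1000) == 1L))
})

test_that("RR requirements match geometric moments and distribution", {
  set.seed(101)
  draws <- rr_requirement(schedule_config("RR", 4), 1e5)
  p <- 1 / 4
  se <- sqrt((1 - p) / p^2) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 4), 3 * se)

  # RR8: chi-square goodness of fit against geometric(1/8)
  draws8 <- rr_requirement(schedule_config("RR", 8), 2e4)
  kmax <- 30
  obs <- tabulate(pmin(draws8, kmax + 1), nbins = kmax + 1)
  probs <- stats::dgeom(0:(kmax - 1), prob = 1 / 8)
  probs <- c(probs, 1 - sum(probs))
  gof <- suppressWarnings(stats::chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("RR config errors on invalid ratio and wrong kind", {
  expect_error(schedule_config("RR", 0.5), ">= 1")
  expect_error(rr_requirement(schedule_config("RT", 120)), "not an RR")
})

test_that("RT deliveries form a Poisson process with the stated mean", {
  cfg <- schedule_config("RT", 120)
  expect_identical(rt_delivery_times(cfg, 0), numeric(0))
  expect_error(rt_delivery_times(cfg, -5), "non-negative")

  set.seed(202)
  counts <- replicate(2000, length(rt_delivery_times(cfg, 3600)))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 30), 3 * se)

  # magazine schedule: mean interval ~60 s via the rate estimator
  # (total time / total deliveries; pooled realized gaps are biased low
  # because the final interval of each session is right-censored)
  cfg60 <- schedule_config("RT", 60)
  c60 <- replicate(2000, length(rt_delivery_times(cfg60, 1800)))
  interval_hat <- 1800 / mean(c60)
  se_int <- interval_hat * (sd(c60) / sqrt(length(c60))) / mean(c60)
  expect_lt(abs(interval_hat - 60), 3 * se_int)

  # distributional check free of censoring: one long realization
  long_gaps <- diff(rt_delivery_times(cfg60, 6e5))
  expect_lt(abs(mean(long_gaps) - 60),
            3 * sd(long_gaps) / sqrt(length(long_gaps)))
})

test_that("RT intervals are memoryless: mean residual equals mean interval", {
  set.seed(303)
  cfg <- schedule_config("RT", 90)
  resid <- replicate(3000, {
    t <- rt_delivery_times(cfg, 5000)
    probe <- 1000  # inspect the process at an arbitrary fixed time
    nxt <- t[t > probe]
    if (length(nxt)) nxt[1] - probe else NA_real_
  })
  resid <- resid[!is.na(resid)]
  expect_lt(abs(mean(resid) - 90), 3 * sd(resid) / sqrt(length(resid)))
})

test_that("chain state machine follows the insert/deliver/retract protocol", {
  stream <- data.frame(time = c(1, 2), lever = c("left", "right"))
  ev <- run_chain_session(schedule_config("RR", 1), stream, duration = 100)
  expect_identical(
    ev$kind[ev$time == 1],
    c("lever_press_left", "lever_insert_right"))
  expect_identical(
    ev$kind[ev$time == 2],
    c("lever_press_right", "sucrose_delivery", "lever_retract_right"))

  # right presses without a completed requirement never deliver
  only_right <- data.frame(time = 1:10, lever = "right")
  ev2 <- run_chain_session(schedule_config("RR", 1), only_right, 100)
  expect_equal(sum(ev2$kind == "sucrose_delivery"), 0)
  expect_equal(sum(ev2$kind == "lever_press_right"), 10)
})

test_that("CRF right-lever sessions reinforce every press up to the cap", {
  stream <- data.frame(time = seq_len(40), lever = "right")
  ev <- run_chain_session(schedule_config("CRF"), stream, duration = 100,
                          cap = 30)
  expect_equal(sum(ev$kind == "sucrose_delivery"), 30)
  expect_equal(sum(ev$kind == "lever_press_right"), 40)
})

test_that("chain conservation: deliveries match completions, never exceed cap", {
  set.seed(404)
  for (rep in 1:20) {
    n <- 60
    stream <- data.frame(
      time = sort(runif(n, 0, 600)),
      lever = sample(c("left", "right"), n, replace = TRUE,
                     prob = c(0.7, 0.3)))
    cap <- sample(1:5, 1)
    ev <- run_chain_session(schedule_config("RR", 2), stream, 600,
                            cap = cap)
    n_del <- sum(ev$kind == "sucrose_delivery")
    expect_lte(n_del, cap)
    # every delivery is preceded by an insertion and coincides with a
    # right press
    expect_equal(sum(ev$kind == "lever_retract_right"), n_del)
    expect_gte(sum(ev$kind == "lever_insert_right"), n_del)
  }
})

test_that("closed-loop trigger fires once per delivery on the first lick", {
  expect_identical(closed_loop_trains(c(100, 200), numeric(0)), list())

  tr <- closed_loop_trains(100, c(100.8, 101.0), latency = 0.015)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$onset, 100.815)
  expect_length(tr[[1]]$pulse_onsets, 100)  # floor(20 Hz * 5 s)
  expect_true(all(tr[[1]]$pulse_onsets >= tr[[1]]$onset &
                    tr[[1]]$pulse_onsets <= tr[[1]]$onset + 5))

  # 30 deliveries each followed by a lick: exactly 30 trains, each within
  # its delivery window
  set.seed(11)
  deliveries <- cumsum(runif(30, 60, 180))
  licks <- sort(deliveries + runif(30, 1, 5))
  trains <- closed_loop_trains(deliveries, licks, latency = 0.015)
  expect_length(trains, 30)
  onsets <- vapply(trains, `[[`, numeric(1), "onset")
  win <- findInterval(onsets, deliveries)
  expect_identical(win, seq_len(30))
})

test_that("a delivery during an active train defers its trigger window", {
  # Second delivery arrives 2 s into the first train; the lick at 102.5
  # falls inside the active train and must not trigger; the first lick
  # after the train end (105.02) does.
  deliveries <- c(100, 102)
  licks <- c(100.0, 102.5, 106.0)
  trains <- closed_loop_trains(deliveries, licks, latency = 0.02)
  expect_length(trains, 2)
  expect_equal(trains[[1]]$onset, 100.02)
  expect_equal(trains[[2]]$onset, 106.02)

  # lick exactly at the delivery time counts ("at or after")
  tr <- closed_loop_trains(50, 50, latency = 0.01)
  expect_equal(tr[[1]]$onset, 50.01)
})

test_that("latency outside [0, 1) is a config error", {
  expect_error(closed_loop_trains(1, 2, latency = 1.5), "latency")
  expect_error(closed_loop_trains(1, 2, latency = -0.01), "latency")
})

test_that("yoked trains copy the source exactly and ignore target behavior", {
  set.seed(5)
  src <- closed_loop_trains(c(100, 300, 500),
                            c(101, 301, 501), latency = 0.015)
  target_a <- lick_session_fixture(licks = c(7, 8, 9), duration = 3600)
  target_b <- lick_session_fixture(licks = c(2000, 2001), duration = 3600)
  ya <- yoke_trains(src, target_a)
  yb <- yoke_trains(src, target_b)
  expect_identical(lapply(ya, `[[`, "onset"), lapply(src, `[[`, "onset"))
  expect_identical(ya, yb)  # behavior independence
  expect_identical(yoke_trains(list(), target_a), list())

  short <- lick_session_fixture(licks = numeric(0), duration = 200)
  expect_warning(kept <- yoke_trains(src, short), "dropped")
  expect_length(kept, 1)
})
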