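---
title: "Lick microstructure and incentive-learning analysis with lickcraft"
author: "lickcraft authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lick microstructure and incentive-learning analysis with lickcraft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The behavioral problem

Incentive learning asks how an animal updates the *value* of an outcome —
separately from how it later *uses* that value to decide whether to act.
The task this package analyzes is the mouse version of the classic design:

1. **Training.** Under a fixed daily food-restriction schedule (2 h or
   16 h), mice learn a chained response: pressing a left ("seeking") lever
   on a random-ratio (RR) schedule gives access to a right ("taking")
   lever; one right press (FR1) delivers a sucrose solution to a
   lickometer port and retracts the right lever.
2. **Re-exposure.** The restriction schedule is kept or shifted (2→16 h
   raises motivational state, 16→2 h lowers it) and mice receive the same
   sucrose *non-contingently* on a random-time schedule (RT120: mean one
   delivery per 2 min for 60 min). Licking during this session indexes
   palatability; consuming the outcome in the new state is the learning
   opportunity.
3. **Test.** The next day a brief (5 min) non-rewarded session measures
   seeking. Because nothing is delivered, the response rate — expressed as
   a percent of the acquisition baseline — reflects the *remembered*
   outcome value. Values above 100% indicate upward revaluation, below
   100% downward revaluation, and ≈100% indicates no updating (as when
   sucrose was never experienced in the new state, or when updating is
   experimentally blocked even though palatability shifts normally).

The package implements the full measurement chain for this design: event
logs → lick microstructure, percent-of-baseline response analysis with the
standard exclusion rules, the statistical battery, an operant-schedule and
closed-loop-stimulation simulator, and a synthetic cohort generator whose
recorded ground truth lets the whole pipeline be validated with no animal
data.

## Data model and file dialect

A `session()` is one subject's visit: design labels plus a sorted event
table (`time` in seconds from session start, `kind` from a small
vocabulary: lever presses, sucrose deliveries, lick contacts, lever
insertion/retraction, light on/off, magazine entries). Lick contacts are
onset-only; every microstructure metric below uses onsets and
inter-onset intervals. Operant hardware exports are idiosyncratic, so the
package defines its own canonical dialect — a CSV event table
(`time_s,kind,payload_json`) with a JSON metadata sidecar, or a single
JSON document — and `read_session()` / `write_session()` round-trip it
exactly (times are serialized at full precision; unknown event codes are
preserved with a warning rather than dropped). `validate_cohort()` returns
violations as data: sortedness, time bounds, design membership, and
protocol-ordered phases.

## Lick microstructure

Raw lickometer contacts are first debounced with a greedy left-to-right
10 ms window (`debounce_licks()`), matching the minimum bin of contact
lickometers. Bursts are then maximal runs of **two or more licks whose
consecutive inter-lick intervals (ILIs) are strictly under 1 s**
(`segment_bursts()`). Two conventions are worth stating because they are
easy to get subtly wrong:

* *Strict inequality.* An ILI of exactly 1.0 s splits a run. The unit
  tests pin this boundary and verify the segmentation against an
  exhaustive oracle that tests every contiguous run for the burst
  predicate.
* *Onset-only durations.* Burst duration is last-lick onset minus
  first-lick onset; with onset-only data no other definition is
  available.

`lick_microstructure()` assembles the per-session panel: total licks,
licks per 10-min bin, mean latency from a delivery to the first
qualifying lick, burst ratio (licks in bursts over total licks), mean
burst duration, mean licks per burst, mean within-burst ILI (pooled over
all within-burst intervals), the duration and lick count of the *first
burst after each delivery* (consumption-locked metrics), and the latency
to the session's first lick. Post-delivery windows are half-open
`[delivery_i, delivery_{i+1})` so nothing is attributed twice; a burst
already ongoing at the delivery is *not* counted as the first burst
following it (the conservative reading of "first burst following");
deliveries with no qualifying lick or burst are excluded from means, not
imputed to zero. All computation is in seconds; milliseconds are a
presentation choice.

## Response analysis and exclusions

The baseline is the mean response rate of the last two training days
(`baseline_rate()`); the test statistic is
`100 * rate_test / rate_baseline` (`percent_baseline()`). Three exclusion
rules are implemented (`acquisition_filter()`,
`percent_baseline_outlier_filter()`):

* **Acquisition:** a subject must emit at least 15 seeking-lever presses
  in one of its last two training sessions — the concrete form of the
  ">0.25 presses/min over 60 min" criterion. The count rule is operative
  because the two phrasings disagree at exactly 15 presses per hour, and
  the count is the stated concrete minimum; `scripts/acceptance.R`
  recovers the boundary by scanning the filter.
* **Baseline-rate outliers:** strictly more than 2 SD from the cohort
  mean, computed over the acquisition-rule survivors.
* **Percent-baseline outliers:** strictly more than 3 SD from the group
  mean. Note that a |z| > 3 point is only attainable in groups of 11 or
  more (max |z| is `(n-1)/sqrt(n)`), so this rule is inert in very small
  groups.

Both SD rules compute their statistics over the records that passed the
*earlier* filters, which makes every filter idempotent — re-filtering a
filtered cohort changes nothing. Rates always use the actual session
duration, since continuous-reinforcement sessions legitimately vary.

## The statistical battery

`t_unpaired()` uses the pooled-variance test, switching to Welch's
correction when a two-sided F-ratio test on the sample variances rejects
at α = 0.05 — a concrete rule for "if variances were not similar", which
is otherwise unoperationalizable. `t_one_sample()` defaults to a null of
100, the no-revaluation anchor. `anova_factorial()` uses Type-III sums of
squares on sum-to-zero contrasts, the convention that matches unbalanced
behavioral group sizes. `anova_mixed()` fits the classical split-plot
decomposition (between effects against the subject stratum, within
effects against the subject-by-block stratum), requires complete balanced
within-subject data, and applies no sphericity correction, so its degrees
of freedom are the uncorrected textbook ones. Effects with numerically
zero sums of squares are reported as F = 0, p = 1 rather than 0/0.
`bonferroni_pairwise()` multiplies raw p-values by the number of planned
comparisons, capped at 1. Degenerate inputs (zero-variance samples) give
t = 0, p = 1 when the null is exactly satisfied and an explicit error
otherwise — an infinite t is never returned silently.

## The schedule engine

* **RR** requirements are per-press Bernoulli(1/ratio), i.e. geometric on
  {1, 2, ...} with mean equal to the ratio — the standard operant-software
  convention. RR1 degenerates to always-1.
* **RT** deliveries are a homogeneous Poisson process with the stated
  mean interval, truncated at the session end. A subtlety the tests
  encode: the *realized* gaps inside finite sessions are biased low
  because each session's final interval is right-censored, so the mean
  interval is estimated as total time over total deliveries (the rate
  estimator), which is unbiased for the schedule parameter.
* **The chain** (`run_chain_session()`) replays a press stream through
  the state machine: left presses count toward the current requirement
  only while the right lever is retracted; completion inserts the right
  lever; the reinforced right press retracts it and draws a fresh
  requirement; a delivery cap and the session duration bound the session.
  Ineffective presses are recorded, never errors.
* **Closed-loop stimulation** (`closed_loop_trains()`): the first lick at
  or after a delivery (and before the next) triggers one 20 Hz, 5 ms,
  5 s train (100 pulses) at the lick time plus a 10–20 ms hardware
  latency; at most one train per delivery; no re-triggering while a train
  is active — if the next delivery falls inside an active train its
  trigger window starts at the train's end. A lick exactly at the
  delivery time counts ("at or after"). `yoke_trains()` copies trains
  verbatim onto a partner session without consulting its behavior, the
  defining property of a yoked control.

## The synthetic generator

`generative_config()` fixes one group's study conditions. Defaults encode
the design above: 10 subjects per group, two 60-min RR4→FR1 training
sessions, a 60-min RT120 re-exposure, a 5-min non-rewarded test.
Motivational state enters as a multiplier via `restriction_state()`
(2 h → 1.0, 16 h → 1.6, linear in hours between), acting through
power links with exponent 1 — the simplest monotone link that reproduces
the ordinal effects (more restriction: more licks per burst, shorter
latency, higher seeking rate).

Free parameters the source experiments do not quantify were fixed once at
values typical for mouse licking and acquisition and are not tuned:
seeking rate 0.58 presses/min at state 1 (matching reported acquisition
rates), 6 licks per consummatory burst at state 1 (shifted Poisson,
minimum 2), 130 ms mean within-burst ILI (gamma, shape 4; rodent licking
runs at 7–8 Hz, and any value well under the 1 s criterion preserves the
qualitative structure), 4 s mean delivery-to-lick latency (lognormal,
sdlog 0.5), and a 1 lick/min anticipatory Poisson background, which
yields burst ratios around 0.8–0.85. All licks respect the 10 ms
debounce floor; bursts are truncated at the next delivery.

The core generative contract is the **palatability / updating
dissociation**: lick-train distributions depend only on the current
state, while the test-session seeking rate is driven by the *effective*
state — the test state if updating occurred (updating intact *and*
sucrose experienced at re-exposure), otherwise the training state. The
`value_update_intact` switch therefore changes test behavior without
touching re-exposure licking; with a common seed the lick streams are
bit-identical under either setting, which the tests assert directly.
Expected percent baseline is recorded per subject in the ground truth
(100 × f(effective)/f(train)) and is never read by the analysis modules.

With these effect sizes, groups of 8–12 subjects give roughly 0.8 power
for the primary directional contrasts, mirroring realistic group sizes;
single-replicate group means of percent baseline remain noisy because a
5-min test at ~0.6–0.9 presses/min yields only a handful of presses per
subject, exactly as in the real preparation.

What the generator does *not* emulate: learning curves across acquisition
days (training sessions are stationary), satiation within the re-exposure
session, inter-subject parameter heterogeneity beyond process noise, and
any neural effect of the light trains (stimulation is bookkeeping only).
Passing recovery tests therefore shows the analysis chain is correct and
calibrated for data of this structure, not that real mice obey these
distributions.

## Numerical and design choices

* Times are seconds, session-relative; file serialization uses `%.17g`
  so doubles round-trip exactly and repeated writes are byte-identical.
* Bins and post-delivery windows are half-open `[a, b)`; a lick at
  exactly the session end is kept in the last bin so counts always
  partition the total.
* The debounce is greedy left-to-right (a kept lick anchors the next
  window), the same rule lickometer hardware applies online.
* Per-group seeds in `run_pipeline()` are derived deterministically from
  the master seed and stay within 32-bit integer range.
* Validation problem sizes: the segmentation oracle runs on 1,000 random
  trains; the schedule moments use 10,000 simulated sessions; pattern
  recovery uses 500 replicate cohorts of 10 subjects per group; battery
  calibration uses 2,000 null replicates per test with a 3.5-binomial-SE
  simultaneous band over the nine checks.

## Worked pipeline run

```{r}
library(lickcraft)

configs <- list(
  generative_config(n_subjects = 8),                           # 2 -> 2
  generative_config(n_subjects = 8, restriction_test_hr = 16)) # 2 -> 16
bundle <- run_pipeline(run_config(
  "synth", configs, out_dir = "results_demo", seed = 42))

# group means of the consummatory metrics and the revaluation score
aggregate(cbind(total_licks, post_delivery_burst_licks, burst_ratio)
          ~ group, bundle$microstructure, mean)
aggregate(percent_baseline ~ group, bundle$response_records, mean)
bundle$stats
```

The shifted group shows more licks, larger post-delivery bursts, and a
percent baseline above 100; the unshifted group stays near 100. The
bundle directory contains the same tables as CSV plus the config
snapshot, the exclusion log, and the generator's ground truth.

## Known limitations

* The mixed ANOVA handles one within-subject factor (time/session
  blocks) with one or two between factors — the designs used here — and
  refuses incomplete data rather than imputing.
* Inferential statistics from the original animal experiments are not
  reproduction targets: those data are not public, so validation is
  property-based (oracle equivalence, calibration, parameter recovery,
  schedule moments) rather than a numeric replay of reported t and F
  values.
* The importer reads only the package's own dialect; native operant
  logger annex formats need a converter upstream.
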