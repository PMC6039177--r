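# lickcraft

Analysis tools for mouse **incentive-learning** experiments: the paradigm
in which an animal trained to seek an outcome (here, sucrose earned by a
chained random-ratio → fixed-ratio-1 lever sequence) must *experience*
that outcome in a changed motivational state — longer or shorter daily
food restriction — before the new value controls its decisions. The
package covers the full measurement chain:

* **Lick microstructure** — debouncing (10 ms), burst segmentation
  (maximal runs of ≥ 2 licks with inter-lick intervals strictly under
  1 s), and the standard palatability panel: total licks, licks per
  10-min bin, burst ratio, licks per burst, burst duration, within-burst
  inter-lick interval, latency to lick after a delivery, and the first
  consummatory burst following each delivery.
* **Response analysis** — acquisition baselines (mean of the last two
  training days), the percent-of-baseline revaluation score
  `100 × rate_test / rate_baseline`, and the standard exclusion rules
  (minimum 15 presses in a last-two-days session; baseline rates > 2 SD
  from the cohort mean; percent-baseline scores > 3 SD from the group).
* **Group statistics** — pooled/Welch unpaired t, paired t, one-sample t
  against 100 %, Type-III factorial ANOVA, split-plot mixed ANOVA
  (uncorrected dfs), Bonferroni-corrected planned comparisons.
* **Schedule simulation** — random-ratio (per-press Bernoulli),
  random-time (Poisson) and chained RR→FR1 sessions; closed-loop
  lick-triggered light trains (20 Hz, 5 ms pulses, 5 s; 10–20 ms trigger
  latency) and exact yoked copies.
* **Synthetic cohorts** — a generator with recorded ground truth that
  reproduces the structure the analysis assumes, including the key
  dissociation: palatability (licking) follows the *current* state,
  while test-day seeking follows the *updated* value only if updating
  occurred.

## Worked example

Simulate a positive incentive-learning experiment — one group kept at 2 h
food restriction throughout, one shifted from 2 h to 16 h before
re-exposure — and run the full pipeline:

```r
library(lickcraft)

configs <- list(
  generative_config(n_subjects = 8),                           # 2 -> 2
  generative_config(n_subjects = 8, restriction_test_hr = 16)) # 2 -> 16
bundle <- run_pipeline(run_config(
  "synth", configs, out_dir = "results_demo", seed = 42))

aggregate(cbind(total_licks, post_delivery_burst_licks, burst_ratio)
          ~ group, bundle$microstructure, mean)
#>   group total_licks post_delivery_burst_licks burst_ratio
#> 1  2-16         326                      9.79       0.829
#> 2   2-2         242                      6.07       0.754

aggregate(percent_baseline ~ group, bundle$response_records, mean)
#>   group percent_baseline
#> 1  2-16           167.33
#> 2   2-2            74.47

bundle$stats
#>           test_name       effect statistic df       p
#> 1 one-sample t-test 2-16 vs 100%      3.39  7 0.01155
#> 2 one-sample t-test  2-2 vs 100%     -1.54  7 0.16730
#> 3   unpaired t-test  2-16 vs 2-2      3.59 14 0.00295
```

The shifted group licks more and packs more licks into its
post-delivery bursts (palatability tracks the raised state), and its
non-rewarded test responding is significantly above its acquisition
baseline — upward revaluation — while the unshifted group does not
differ from 100 %. `results_demo/` holds the same tables as CSV plus the
config snapshot, exclusion log, and the generator's ground truth. The
`vignettes/` directory explains the model, every convention (strict
inequality at the 1 s burst criterion, half-open post-delivery windows,
exclusion-filter idempotence), and the generator's assumptions.

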