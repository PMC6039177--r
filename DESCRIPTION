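Package: lickcraft
Title: Lick Microstructure and Incentive Learning Analysis for Operant
    Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing operant behavioral sessions from
    incentive-learning experiments in rodents: debouncing and burst
    segmentation of lickometer contact trains, the standard panel of lick
    microstructure statistics (burst ratio, licks per burst, within-burst
    inter-lick interval, post-delivery burst metrics), lever-press response
    rates and percent-of-baseline revaluation tests with the usual
    acquisition and outlier exclusion rules, and the accompanying
    statistical battery (pooled/Welch t-tests, one-sample tests against
    baseline, Type-III factorial and split-plot mixed ANOVA, Bonferroni
    post hocs).  Also provides a simulator for chained random-ratio /
    fixed-ratio schedules, random-time delivery schedules, closed-loop
    lick-triggered stimulation with yoked controls, and a synthetic cohort
    generator with recorded ground truth so the whole pipeline can be
    exercised and validated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
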