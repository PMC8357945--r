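Package: somnogram
Title: Simulation, Scoring and Architecture Analysis of Rodent Polysomnography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rule-based sleep scoring of rodent electroencephalogram
    (EEG) and electromyogram (EMG) recordings and for the downstream analysis of
    sleep architecture. Provides a semi-Markov polysomnography simulator that
    emulates a cage-change (first-night-effect) experiment with probiotic- and
    antihistamine-like treatment arms, per-epoch spectral band-power computation
    (delta/theta/sigma/beta EEG bands and 32-64 Hz EMG power on 8-s epochs),
    threshold-based wake/NREM/REM staging, the full suite of hypnogram
    architecture metrics (state totals, episode counts, bout-length histograms,
    state transitions, NREM interruptions, sleep latency, hourly dynamics and
    relative NREM-delta power), and the group-comparison layer (one-way ANOVA
    with Tukey HSD, two-way ANOVA with Bonferroni-corrected cell contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    emmeans,
    generics,
    ggplot2,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
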