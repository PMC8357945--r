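# somnogram

Rule-based sleep scoring and architecture analysis for rodent
polysomnography, with a generative simulator of the cage-change
(first-night-effect) experiment.

## The problem

Rodent sleep studies score vigilance from two channels — cortical EEG
(125 Hz) and neck EMG (250 Hz) — on 8-s epochs. Per epoch, EEG power is
integrated into delta (0.16–4 Hz), theta (6–9 Hz), sigma (10–14 Hz) and
beta (14–32 Hz) bands from 16-s FFT windows with 50% overlap, and EMG power
over 32–64 Hz from 2-s windows. The state rules are:

| state | EMG power | sigma×theta | delta |
|---|---|---|---|
| Wake | high | low | — |
| NREM | low | high | high |
| REM | low | high | low |

"High" and "low" are per-animal thresholds that this package fits by
two-component Gaussian splits on log powers. The scored hypnogram then
yields the architecture metrics used to quantify sleep disturbance and its
rescue: state totals per Zeitgeber-time window, episode counts, bout-length
histograms (e.g. wake bouts > 300 s), transitions per hour, NREM
interruptions, sleep latency (first NREM bout longer than 5 min), hourly
state profiles, cumulative REM accumulation, and relative NREM-delta power.
Group comparisons use one-way ANOVA with Tukey HSD and two-way
(handling × treatment) ANOVA with Bonferroni-corrected cell contrasts.

Because real recordings need animals, the package ships a semi-Markov
simulator that emulates the experiment — tail-handled (TH) vs cage-change
(CC) handling crossed with vehicle, antihistamine-like (DIPH: REM
suppression, NREM fragmentation) and probiotic-like (PS150: restored sleep
onset) arms — so the whole pipeline is verifiable against known ground
truth. It is intended for method validation, power exploration and
teaching, not as a substitute for animal data.

## Worked example

Simulate a small TH/CC vehicle cohort (2 animals per cell, 2 h from ZT 0),
score it blind to the ground truth, and summarize:

```r
library(somnogram)

cfg <- run_config(cohort_design(n_per_group = 2, handling = c("TH", "CC"),
                                treatment = "Veh", duration_h = 2, seed = 42))
run <- run_pipeline(cfg)
run
#> <psg_run> 4 animals, staging agreement 0.973

run$confusion          # scored vs ground-truth epochs, pooled
#>      scored
#> truth    W    N    R
#>     W 2269    0    0
#>     N    1 1128   95
#>     R    0    0  107

subset(run$metrics, metric == "latency_s",
       select = c(animal_id, handling, value, censored))
#>   animal_id handling value censored
#> 1 TH-Veh-01       TH  2912        0
#> 2 TH-Veh-02       TH   152        0
#> 3 CC-Veh-01       CC  3920        0
#> 4 CC-Veh-02       CC  7200        1
```

Staging recovered 97.3% of the 7200 scored epochs (the misses are NREM/REM
boundary epochs, whose 16-s analysis windows straddle the transition).
Sleep latencies — seconds to the first NREM bout longer than 300 s — are
markedly longer in the cage-changed animals; `CC-Veh-02` never produced a
qualifying bout inside the 2-h recording, so its latency is censored at the
recording length. At the study's scale (8 h, n = 8 per cell) these
group differences are what the statistics layer (`cohort_stats()`,
`anova_twoway_bonferroni()`) tests formally.

Individual stages are ordinary functions on tibbles and chain with the
pipe:

```r
d      <- cohort_design(duration_h = 8, seed = 7)
truth  <- sample_hypnogram(d, animal_index = 1, handling = "CC")
series <- synthesize_signals(truth) |> band_power_series()
hyp    <- classify_epochs(series, fit_thresholds(series))
summarize_architecture(hyp, series, windows = list(light = c(0, 8 * 3600))) |>
  tidy()
```

`autoplot()` methods draw hypnograms and band-power traces; a thin CLI over
the same functions is in `inst/scripts/somnogram-cli.R`
(`simulate | spectra | stage | metrics | stats | run`).

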