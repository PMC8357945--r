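---
title: "Methods: simulation, scoring and architecture analysis of rodent polysomnography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, scoring and architecture analysis of rodent polysomnography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnogram)
```

## The scoring problem

Rodent sleep is scored from two channels: cortical EEG, digitized at 125 Hz
after an analog band-pass of 0.16–53.05 Hz, and dorsal-neck EMG at 250 Hz
after 0.72–112.88 Hz. Each 8-s epoch receives one of three vigilance
states:

* **Wake** — high EMG power, low sigma\*theta EEG power;
* **NREM sleep** — low EMG, high sigma\*theta, high delta power;
* **REM sleep** — low EMG, high sigma\*theta, low delta power.

The spectral features come from Fourier analysis: EEG on 16-s windows with
50% overlap, integrated into delta (0.16–4 Hz), theta (6–9 Hz), sigma
(10–14 Hz) and beta (14–32 Hz) powers; EMG on 2-s windows integrated over
32–64 Hz. The sigma\*theta product is the sleep-versus-wake EEG
discriminant; delta separates NREM from REM within sleep.

`somnogram` implements this chain end to end — spectral decomposition
(`band_power_series()`), per-animal threshold fitting (`fit_thresholds()`),
epoch classification (`classify_epochs()`), architecture metrics
(`summarize_architecture()`), and cohort statistics (`cohort_stats()`) —
together with a generative simulator of the cage-change (first-night-effect,
FNE) experiment so that every stage can be validated against known ground
truth without animal data.

## Spectral decomposition

**Window placement.** With a 16-s window and an 8-s hop the overlap is 50%
and each epoch receives exactly one estimate: the window centred on it
(covering the epoch plus 4 s on either side). The first and last epochs use
the nearest fully contained window. The centring choice means an epoch
adjacent to a state transition sees up to a quarter of its window from the
neighbouring state; this is the dominant source of residual scoring error
on synthetic data and mirrors the ambiguity of transitional epochs in real
recordings.

**Taper and detrending.** Each window is demeaned and Hann-tapered before
the FFT. The sources describing the original acquisition are silent on the
taper; a Hann window is the standard leakage control, and because staging
compares powers of the same epoch against per-animal thresholds, absolute
scale factors introduced by the taper are irrelevant (powers are homogeneous
of degree 2 in signal amplitude, which the tests verify directly).

**Band integration.** A frequency bin belongs to a band if
`lo <= f < hi`. The half-open rule keeps adjacent bands such as sigma
(10–14 Hz) and beta (14–32 Hz) from double-counting the shared 14-Hz edge,
and the deliberate gaps of the band plan (4–6, 9–10 Hz) are preserved as
printed. At 0.0625-Hz resolution the bands hold 61, 48, 64 and 288 bins
respectively, which is the exact expectation used by the white-noise
calibration test.

**Channel filtering.** The acquisition band-pass is modelled as the
zero-phase (forward–backward) magnitude response of an order-2 Butterworth
high-pass cascaded with an order-9 Butterworth low-pass. `bandpass()`
applies it exactly in the frequency domain — a direct-form recursion at a
0.16-Hz edge on a 125-Hz signal is numerically fragile, whereas the
frequency-domain application is exact and meets the pass/stopband contracts
(mid-band gain within 5%, more than 20 dB attenuation one octave outside
either edge). Because the pipeline only consumes windowed spectra, the
default path (`filter_domain = "stft"`) applies the same response to each
window's power spectrum instead of to the full-length signal; the
`"time"` option filters the raw samples first, and a test verifies the two
routes agree to within 2% on every band.

**EMG aggregation.** The four 2-s windows inside an epoch are averaged,
which is robust to a single noisy sub-window and preserves units. Whether
the original system integrated amplitude or power spectra is not stated;
power is assumed, and since staging uses within-animal order comparisons the
choice is absorbed by the threshold fit.

## Threshold fitting and classification

The scoring rules name "high" and "low" comparisons but no cut values, so
cuts are fitted per animal: each discriminant's log10 power distribution is
split into two Gaussian components (EM via mclust, run under a fixed seed so
fits are reproducible) and the cut placed at the equal-posterior point
between the component means. When the mixture fit fails or the components
are not separated (standardized separation below 0.5), the fallback is the
midpoint of the 25th and 75th log-power percentiles. The delta cut is
fitted only on epochs already below the EMG cut, because the NREM/REM delta
contrast is defined within sleep. A constant channel is a hard error that
names the flat channel.

Classification follows fixed precedence: EMG above its cut is wake,
regardless of the EEG; among low-EMG epochs, sigma\*theta at or below its
cut fits neither sleep description and is scored wake ("quiet wake",
counted in the hypnogram's attributes — a conservative tie rule that avoids
inventing sleep); the rest are NREM when delta exceeds its cut and REM
otherwise. The rules use only order comparisons, so classification is
invariant to a common rescaling of powers and thresholds, and the wake set
shrinks monotonically as the EMG cut rises — both checked as properties.

Smoothing (`smooth_hypnogram()`) exists as an explicit surrogate for manual
rescoring — runs shorter than `min_run` are absorbed when both flanking
runs agree — but the default pipeline applies none, since the original
correction step was manual and non-algorithmic.

## The synthetic cohort

The simulator inverts the staging rules into a generative model.

**State sequence.** A semi-Markov chain on the 8-s grid: log-normal dwell
times per state (positive and right-skewed, matching the long-tailed wake
bout distributions seen in this preparation), rounded up to whole epochs;
REM reachable only from NREM, wake from both sleep states — standard rodent
sleep physiology, consistent with analyses that report only wake–NREM and
NREM–REM transitions. A two-regime switch at ZT 12 modulates dwell means
and the NREM→REM probability (higher sleep pressure in the light phase;
long wake bouts in the dark phase). Brief arousals interrupt interior
epochs of NREM bouts at a small per-epoch rate and return to NREM, which is
the process behind the NREM-interruption metric.

**Default dwell and transition parameters** give a light-phase occupancy of
roughly 35% wake, 58% NREM and 7% REM with mean light-phase bouts of
250 s (wake), 400 s (NREM) and 120 s (REM) — typical of baseline C57BL/6
sleep. `stationary_occupancy()` computes the implied occupancy in closed
form (embedded-chain stationary distribution weighted by expected dwell in
epochs), and a test checks long simulations converge to it.

**Spectral signatures.** Per state, the EEG is a sum of band-limited
Gaussian noise components scaled by band amplitudes plus a low 1/f
background, and the EMG is 32–64 Hz noise scaled by the state's EMG
amplitude over a small broadband floor. Default amplitudes encode
delta-dominant NREM, theta-dominant REM, broadband low-amplitude wake EEG,
and the EMG ordering wake > NREM ≥ REM (REM atonia); constructor-level
invariants reject parameter sets that break the rule structure. Units are
arbitrary: the sources do not characterize absolute microvolt scales after
amplification, and staging is scale-free. Synthesis happens per epoch in
the frequency domain — the bands occupy disjoint bins, so one inverse FFT
per epoch segment yields the full mixture — and segments are overlap-added
with complementary linear ramps spanning 0.5 s, realizing the amplitude
cross-fade at state boundaries (real transitions are not instantaneous, and
the fade avoids spectral splatter at boundaries). An optional 12-bit
quantizer emulates the acquisition ADC and is off by default in tests.

**The FNE manipulation.** Cage-changed (CC) animals start with a wake dwell
drawn from an inflated distribution (mean 3000 s versus the 250-s baseline),
carry a 2-h early-light regime of lengthened wake and shortened NREM
dwells, and have NREM→REM entry suppressed over the first three hours
(multipliers 0, 0.3, 0.7) — prolonged sleep onset, reduced light-phase
NREM, delayed REM recovery. Tail-handled (TH) animals use baseline
parameters throughout.

**Treatment presets.** The antihistamine-like arm (DIPH) halves the REM
dwell mean and quadruples the brief-arousal rate — REM suppression plus
NREM fragmentation; the probiotic-like arm (PS150) shortens the
FNE-inflated initial wake dwell to one third and nothing else — restored
sleep onset without REM cost. The vehicle arm is unmodified. These
magnitudes were chosen once, as plausible effect sizes for an n = 8 design,
and define the planted-effect recovery conditions.

**What the simulator does not emulate.** No spindle or K-complex
morphology, no theta peak drift, no artifacts or electrode noise, no
inter-animal spectral variability beyond the stochastic dwell process.
Passing round-trip tests therefore demonstrates the internal consistency of
the scoring chain at realistic spectral contrast, not performance on real
recordings with artifacts — which the original workflow handled by manual
inspection, explicitly out of scope here.

## Architecture metrics

All metrics are defined on the maximal-run episode decomposition and are
verified against independent brute-force scans on randomized hypnograms
(10^4 cases in the validation suite), alongside conservation laws: state
totals sum to the window length, bout histograms sum to episode counts, and
transitions sum to episodes minus one.

Decisions worth recording:

* **Sleep latency** reads "longer than 5 min" strictly: the first NREM
  episode with duration > 300 s, i.e. at least 38 epochs (38 × 8 = 304 s).
  A fully awake animal has undefined latency, reported as a censored value
  at the recording span so group statistics need not drop it; a
  `drop_censored` sensitivity re-run is available in `cohort_stats()`.
* **NREM interruption**: a wake episode of at most 64 s (8 epochs) flanked
  by NREM on both sides. The term has no printed definition; the cap is
  configurable and carried in the summary metadata.
* **Windows** are half-open ZT intervals; epochs belong by start time.
  Episodes straddling a boundary are truncated for totals but counted once
  — in the window containing their start — for episode counts, and a
  transition is attributed to the window containing the second episode's
  start. Totals therefore conserve exactly while counts are never split.
* **Relative NREM-delta** is normalized within animal to the light-phase
  NREM-delta mean, removing amplitude nuisance without reference to other
  animals; hours with no NREM epochs are undefined rather than zero.
* **REM accumulation** is emitted both per hour and cumulatively, since
  "accumulated amount in each hour" admits both readings.

## Cohort statistics

Group comparisons use the two procedures of the original analysis plan:
one-way ANOVA with Tukey's HSD across groups, and two-way ANOVA
(handling × treatment) with Bonferroni-corrected planned cell contrasts —
pairwise treatments within each handling level and pairwise handling within
each treatment level, each family corrected by its own contrast count.
Sums of squares are Type II, which coincides with the classical
decomposition on balanced designs (checked numerically). Zero total
variance yields an explicit "no test" result rather than an error.
Normality and homoscedasticity are not tested, matching the original plan;
this is a documented limitation. Per-hour treatment tests are emitted
uncorrected across hours, as the original per-hour analysis was described,
with correction available via `p.adjust` on the returned table if desired.

Both procedures are calibrated under null simulations (1000 replicates in
the validation suite) to hold their nominal 5% type-I error.

## Problem sizes and determinism

The validation suite simulates the full study geometry where it matters —
48 animals (6 cells × 8) at 8 h for the staging round trip — and smaller
cohorts elsewhere; metric oracles run on 10^4 randomized hypnograms and
planted-effect recovery on 100 replicate cohorts at the hypnogram level
(staging fidelity being established separately by the signal-level round
trip). Every random draw sits under an explicit seed: per-animal streams
are derived by hashing the design seed with the cell and animal index, so
regenerating a cohort is byte-identical and enlarging it leaves existing
animals unchanged. `run_pipeline()` writes every intermediate as plain
delimited text plus the exact configuration as YAML, and reruns of the same
configuration produce identical files.

## Known limitations

* The generator's realism is spectral-statistical only; morphology-based
  scorers or artifact-handling cannot be evaluated against it.
* Threshold fitting assumes each discriminant is bimodal within the
  recording. Recordings lacking a state entirely (e.g. no REM within a
  short, heavily suppressed window) push the delta split toward a
  within-NREM cut; in the study geometry (8-h recordings) all states are
  present. Very short recordings warn below 50 epochs.
* EDF input/output is not provided; signals are read and written as
  delimited text (`channel, time, value`), which keeps every artifact of a
  run diffable and platform-neutral.
* Censoring of undefined latencies at the window length biases group means
  toward the null when sleep onset never occurs; the sensitivity re-run
  excludes censored animals instead.
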