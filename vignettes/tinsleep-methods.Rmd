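---
title: "Methods: behavioural tinnitus indexing and sleep EEG analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioural tinnitus indexing and sleep EEG analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tinsleep)
```

`tinsleep` implements the quantitative pipeline of a ferret
noise-overexposure (NOE) tinnitus study: behavioural tinnitus indexing from
operant gap- and silence-detection tasks, auditory brainstem response (ABR)
change metrics, sleep-architecture and EEG spectral analysis, and
vigilance-state-resolved auditory evoked response (AER) magnitudes. Because
no raw recordings are distributed with studies of this kind, every analysis
module is paired with a synthetic-data generator with known ground truth, so
that the full pipeline can be exercised end to end and its estimators
validated by parameter recovery.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices made where the procedure is genuinely open,
and what the synthetic validation does and does not establish about real
data.

## Behavioural scoring and the psychometric model

In the silent-gap detection task an animal reports, trial by trial, whether
a noise burst contained silent gaps (lengths 3, 5, 10, 20, 50, 100 or
270 ms) or not. Scoring uses hit rate — the proportion of correct responses
on gap trials — rather than d-prime, because a continuous phantom sound
biases both hits and false alarms in the same direction and d-prime would
cancel the effect of interest.

Filtering rules are read strictly as stated for the paradigm: correction
trials are excluded; gap-task trials with response times above 5 s are
excluded (a trial at exactly 5 s is retained); a session is dropped iff
*more than* 5 gap lengths each have *fewer than* 5 presentations; in the
silence task, trials above 20 s and sessions with fewer than 5 trials of
any stimulus class are excluded. All filters are idempotent.

Hit rates are averaged per session, then across sessions, and a
four-parameter sigmoid

$$p(g) = \mathrm{lo} + (\mathrm{hi}-\mathrm{lo})\,
  \bigl(1 + e^{-b(\log g - m)}\bigr)^{-1}$$

is fitted by least squares on the log-gap axis (the seven gap lengths span
almost two decades; the log axis stabilises the fit). The detection
threshold is the gap length whose fitted hit rate lies closest to 0.5,
found by dense evaluation over [3, 270] ms (0.01-ms steps below 10 ms,
0.1-ms above; ties break toward the shorter gap). The slope at threshold is
the analytic derivative of the fitted curve with respect to gap length in
ms — the axis thresholds are reported on. Fits whose absolute slope at
threshold exceeds 10 times the median across all supplied fits are
excluded; the median is taken jointly across animals, stimuli and
conditions. Fitted curves that never cross 0.5 carry a `not_crossing` flag
and are excluded from threshold-based metrics, since the procedure defines
no threshold for them.

### The normalized threshold scale

For the threshold change metric, the seven gap lengths are mapped onto an
evenly spaced performance scale: 3 ms is 100% and each step down subtracts
100/7 points (85.71, 71.43, 57.14, 42.86, 28.57, 14.29). The published
six-value listing omits the 28.57 step; the full seven-step evenly spaced
scale is used here, treating the omission as typographical. Because fitted
thresholds are continuous, `normalize_threshold()` interpolates linearly on
the log-gap axis between the anchor values by default (thresholds are
"fitted on a continuous scale"); a variant that snaps to the nearest gap
length on the log axis first is available (`method = "snap"`).

## The tinnitus index

The behavioural tinnitus index is the exact sum of three signed change
metrics comparing post-exposure (Post) with baseline (BL) performance:

$$\mathrm{TI} = M_{\mathrm{cont}} + M_{\mathrm{thresh}} + M_{\mathrm{silence}}$$

with

* $M_{\mathrm{cont}} = \mathrm{Post}/\mathrm{BL} - 1$ on the proportion
  correct in no-gap (continuous sound) trials, pooled across stimuli with
  sessions weighted equally — a continuous phantom sound should make
  continuous sounds easier to report;
* $M_{\mathrm{thresh}} = 1 - \mathrm{Post}/\mathrm{BL}$ on the normalized
  thresholds, averaged across stimuli *before* taking the ratio (the
  alternative, averaging per-stimulus ratios, is exposed as
  `thresh_average = "after_ratio"`);
* $M_{\mathrm{silence}} = 1 - \mathrm{Post}/\mathrm{BL}$ on the proportion
  correct in silence trials — tinnitus filling silence should impair
  silence detection.

Each metric is 0 when performance is unchanged and positive in the
direction consistent with tinnitus. The metrics are deliberately *not*
clamped to [0, 1]: negative values (improvements) are informative and
clamping would hide direction.

## ABR quantification

ABR magnitude is the RMS of the averaged waveform inside a response window
of 1.6–4 ms after stimulus onset at the highest level (90 dB SPL), shifted
0.16 ms later per 10 dB decrement to track response latency. A
level–response curve of RMS versus level is integrated by the trapezoidal
rule to a single area (the simplest rule consistent with a six-point
curve), and the magnitude change metric is the percent change of the
stimulus-averaged area, $(\mathrm{Post}/\mathrm{BL} - 1)\times 100$.
Click stimuli are supported but excluded from the change-metric averages by
default, which are defined over the narrowband and broadband noise stimuli.

Thresholds in such studies are scored manually and blind; an automated
surrogate is required for testable software. A wave is deemed present at a
level when the response-window RMS exceeds the mean plus $k$ SD (default
$k = 3$) of the per-level pre-stimulus RMS values (baseline window
$[-1, 0)$ ms); the threshold is the lowest level at which the wave is
present and remains present at every higher level, with a 90 dB SPL ceiling
when no level shows a response. Outputs carry the label
`automated-surrogate` to keep the distinction visible.

The threshold change metric is reported primarily as the threshold
*elevation*, mean(Post) − mean(BL), positive when hearing worsened — the
direction in which elevations are discussed; the literal BL − Post
difference, whose printed sign convention is the opposite, is emitted
alongside (`literal_db`), and the two are always exact negatives.

## Sleep architecture and EEG spectra

Hypnograms label consecutive 4-s epochs as Wake, NREM (slow-wave dominated,
0.5–4 Hz), REM (theta, 4.5–8 Hz, low EMG), REM2 (a ferret-specific
low-voltage 8.5–20 Hz state with low EMG) or Artefact. State percentages
are computed over non-artefact epochs; total sleep is NREM + REM + REM2.
Episodes are maximal runs of a state; artefact epochs *inside* a run bridge
it by default (configurable) but do not count toward its duration, so
episode durations always partition state time. The episode duration
histogram uses bins of <1, 1–5, 5–15, 15–30 and >30 minutes — a repository
choice, as published histograms do not print their bins.

Spectra are per-epoch Hann-tapered periodograms at the native 0.25 Hz
resolution of a 4-s window, one-sided, normalised so that bins sum to the
signal variance (µV² per bin); 0–30 Hz is analysed. Signals at other
sampling rates are first resampled to 256 Hz by polyphase anti-aliased
resampling. Two properties of the Hann taper matter for validation: an
on-grid tone's energy is confined to the three bins of the main lobe
(about two thirds in the central bin and one sixth in each neighbour), so
single-tone concentration checks are evaluated over the main lobe with the
central bin required to be the spectral peak; and band power scales with
amplitude squared, which the slow-wave-activity tests verify exactly by
matched-noise comparisons.

### Spectral outlier exclusion

Residual artefacts confined to single frequency bins are removed by a
bootstrap rule: for each state and bin, the mean and its standard deviation
are estimated from 500 bootstrap resamples of the state's epochs, and epoch
values outside mean ± 600 SD are masked — per bin, not per epoch. The SD
here is the bootstrap SD *of the mean* (both statistics come from the
bootstrap): with $n$ epochs the cut sits at roughly $600/\sqrt{n}$
across-epoch SDs from the mean — about 19 SDs at $n = 1000$ — which is what
makes a 600-fold multiplier exclude "only extreme outliers" rather than
nothing at all. Under the alternative reading (600 across-epoch SDs) the
rule could never remove a $10^4$-fold single-bin outlier from a thousand
epochs, because the outlier inflates the SD it is tested against; that
reading is rejected as inconsistent with the rule's stated purpose. The
multiplier and the SD definition are configurable.

### Slow-wave activity

SWA is EEG power density in 0.5–4 Hz during NREM, implemented as the mean
over the band's bins (power density, not summed band power — the two differ
only by a constant factor of the bin count). The time course averages NREM
epochs within 15-min intervals, marks intervals without NREM as missing,
and merges four 15-min values into each 1-h bin by their mean.

### Automated vigilance scoring

As with ABR thresholds, vigilance states are scored manually in practice;
`score_epochs_auto()` is an explicit surrogate for synthetic-data testing.
An epoch is Wake when EMG power exceeds a threshold (by default placed
between the two modes of the log EMG power distribution by minimising
within-class variance); otherwise the sleep state whose defining band has
the highest relative power wins. On generator-default recordings the
surrogate agrees with the ground-truth hypnogram on more than 90% of
epochs, which is a property of the generator's clean state separation, not
a claim about manually scored field data.

## Auditory evoked responses

Stimulus-locked segments over [−0.5, +5] s are cut at each onset,
downsampled by 2, assigned the vigilance state of the 4-s epoch containing
the onset, and dropped when that epoch is an artefact. Trials whose
stimulus spans a state transition are not treated specially.

Because inter-trial variability prevents reliable peak detection on single
averages, each group (condition × frequency × level × state) is represented
by 20 bootstrapped means — means of with-replacement resamples at full
group size. Each is smoothed with a centred 8-point moving average (the
window shrinks at the edges), and each response component's magnitude is
the window maximum minus the *subsequent* minimum, searched only to the
window's end; a maximum on the last sample yields a missing value rather
than a fabricated magnitude. Component windows (R1, R2, up to R3) are
derived per animal from the smoothed grand mean: peaks within 0–0.5 s
post-onset passing a prominence floor (2 × the pre-stimulus SD of the
smoothed trace, with a 10%-of-maximum guard on quiet traces) anchor windows
of ±80 ms, truncated at midpoints between neighbouring peaks so windows
never overlap. Pooled summaries are means ± SEM over all retained
bootstrap-replicate magnitudes in a cell. An optional trial screen retains
only trials whose SD does not exceed twice the average trial SD
(`sd_screen = 2`), for use with degraded long-term recordings.

## The synthetic-data generators

The generators encode the statistical structure the analysis assumes, with
every parameter recoverable:

* **Behaviour** — Bernoulli responses from the same four-parameter logistic
  family the analysis fits (so recovery is well-posed), parametrised
  directly by the 0.5-crossing threshold; balanced gap/no-gap trials with
  stimuli rotating across sessions; lognormal response times with a small
  probability (2%) of slow outlier trials so the filters have work to do;
  optional flagged correction trials after errors. Silence-task classes
  mix at the paradigm proportions 50% NBN / 30% AM / 20% silence.
* **ABR** — per stimulus, a template of Gabor-like deflections with
  latencies inside the 1.6–4 ms window at 90 dB SPL, shifted 0.16 ms per
  10 dB decrement in register with the analysis window. The averaged
  waveform is zero below threshold and grows linearly above it
  (0.02 µV/dB by default); at threshold itself a just-detectable response
  of one dB-equivalent is present, reflecting the definition of threshold
  as the lowest level that elicits a response — without it, noiseless
  recovery would be systematically one level high. Noise enters as
  Gaussian residue of SD `noise_sd_uv`/√repetitions (700 sweeps).
* **EEG/EMG** — a semi-Markov hypnogram with geometric bout lengths
  (defaults: Wake 2 min, NREM 4 min, REM 80 s, REM2 72 s mean bouts, with
  transition probabilities that put long-run occupancy near one quarter
  wakefulness and three quarters sleep, NREM-dominated); EEG as a pink-
  noise floor plus three band-limited noise processes (0.5–4, 4.5–8,
  8.5–20 Hz) whose amplitudes step per epoch with the state; EMG high in
  Wake, low in sleep; broadband bursts in artefact epochs; and a
  damped-sinusoid evoked template added at schedule onsets with per-state
  gain (defaults Wake 1.0, REM2 0.9, REM 0.75, NREM 0.6) and 10%
  multiplicative trial jitter. Stimulus schedules present each
  frequency × level combination a configured number of times (200 by
  default) in randomised order with 10–42 s uniform inter-stimulus
  intervals.

No quantitative amplitude ranges exist for ferret state-specific EEG, so
the band amplitudes, the pink floor and the evoked template are free
parameters, not estimates of any animal. They were fixed once by a
Monte-Carlo calibration of the pipeline's own recovery properties — gap
thresholds within ±3 ms at 1000 trials/stimulus, ABR thresholds within
±10 dB at 700-sweep noise, and preservation of the configured evoked-gain
ordering at 200 trials per stimulus combination — and are not revisited
per analysis. The calibrated defaults put NREM slow waves at 27 µV SD
against a 5 µV pink floor and evoked components of 150–300 µV, i.e.
clearly separable states and strong epidural-scale evoked responses.

## Problem sizes used in validation

The test suite validates at sizes chosen to complete in minutes on one
processor while preserving the statistical regime: behavioural recovery
uses 200 replicates of 1000 trials per stimulus; ABR recovery 100
replicates of the six-level grid; spectral and outlier checks 200–1000
epochs; the evoked-response ordering check 50 seeds of one frequency at
two levels with 200 presentations per combination (recordings of about
three hours each); and the index directionality check 50 seeds of 15 000
gap trials and 15 000 silence-task trials per condition, sizes at which a
null animal's index varies by well under ±0.05. A full-scale study (four
frequencies, four levels, 48-h recordings) uses the same code paths with
larger inputs.

## What passing tests do and do not show

The generators share their functional families with the estimators
(logistic psychometrics, template ABRs, band-separable states). Passing
recovery tests therefore demonstrates that the pipeline is internally
consistent, unbiased at realistic trial counts, and correctly implements
the stated rules — not that the models are adequate for any particular
animal's data. Real EEG has 1/f structure, state transitions inside
epochs, scorer disagreement and non-stationary artefacts that the
generators deliberately omit (see Non-goals in the documentation). The
manual-scoring surrogates (ABR threshold detection, vigilance scoring)
are labelled as such in their outputs and should not be mistaken for
reproductions of blind human scoring.

## Known limitations

* Group-level inferential statistics (GLMMs, ANOVA families) are out of
  scope; the package emits tidy tables suitable for external model
  fitting.
* The peak-to-subsequent-trough magnitude is upward-biased for very small
  trial groups (noise inflates the extremum statistics); the bootstrap
  means mitigate but do not remove this, exactly as in the original
  procedure. Groups smaller than ~10 trials deserve caution.
* EDF support covers continuous fixed-rate 16-bit recordings — sufficient
  for the pipeline's own files — not the full EDF+ specification.
* Spike-sorting-based cortical analyses and figure aesthetics are not
  reimplemented.
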