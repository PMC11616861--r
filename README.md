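# tinsleep

Quantitative analysis of noise-overexposure (NOE) tinnitus studies in the
ferret: behavioural tinnitus indexing, auditory brainstem response (ABR)
change metrics, sleep architecture and EEG spectral analysis, and
vigilance-state-resolved auditory evoked response (AER) magnitudes — with
synthetic-data generators carrying known ground truth for every modality,
so the whole pipeline can be validated by parameter recovery.

It is written for auditory neuroscientists and sleep researchers who need a
tested, scriptable reimplementation of this analysis family, and for
methodologists who want to probe how its estimators behave under controlled
conditions.

## The models at the core

**Behavioural tinnitus index.** Performance in an operant silent-gap
detection task (gap lengths 3–270 ms) and a silence-detection task is
compared between baseline (BL) and post-exposure (Post):

    TI = M(cont) + M(thresh) + M(silence)

    M(cont)    = Post/BL − 1      (proportion correct, no-gap trials)
    M(thresh)  = 1 − Post/BL      (normalized gap thresholds, %)
    M(silence) = 1 − Post/BL      (proportion correct, silence trials)

Each metric is zero when performance is unchanged and positive in the
direction consistent with tinnitus. Gap thresholds come from four-parameter
sigmoid fits of hit rate versus log gap length, read off at a hit rate of
0.5, and are normalized onto an evenly spaced scale on which 3 ms is 100%
and each step down the seven-gap series subtracts 100/7 points.

**ABR metrics.** The magnitude of an averaged ABR waveform is its RMS in a
1.6–4 ms response window that shifts 0.16 ms later per 10 dB decrement;
the level–response curve is integrated trapezoidally to an area, and the
condition comparison reports the stimulus-averaged threshold elevation (dB)
and the percent change in area, (Post/BL − 1) × 100. Automated threshold
estimates are an explicit surrogate for blind manual scoring and are
labelled as such.

**Sleep and spectra.** Hypnograms on a 4-s epoch grid (Wake, NREM, REM,
REM2, Artefact) give state percentages and episode statistics; EEG power
spectra are per-epoch Hann periodograms at 0.25 Hz resolution, cleaned by a
bootstrap outlier rule (values outside mean ± 600 bootstrap-SDs of the
mean, per state and frequency bin), and summarised as state spectra and
NREM slow-wave activity (0.5–4 Hz) time courses in 15-min and 1-h bins.

**Evoked responses.** Stimulus-locked EEG segments ([−0.5, +5] s) are
grouped by condition × frequency × level × vigilance state; each group is
represented by 20 bootstrapped means, smoothed with an 8-point moving
average, and each response component (R1–R3, windows derived per animal)
is quantified as the window maximum minus the subsequent minimum.

## Worked example

Simulate a baseline animal and a post-exposure animal whose gap thresholds
rose by 25 ms, whose no-gap performance improved, and whose silence
detection dropped, then compute the index:

```r
library(tinsleep)

gt_bl <- behaviour_ground_truth(seed = 1)
gt_post <- behaviour_ground_truth(
  threshold_ms = pmin(gt_bl$threshold_ms + 25, 270),
  nogap_correct = 0.95,
  silence_correct = c(NBN = 0.85, AM = 0.9, silence = 0.65),
  seed = 2)

ti <- compute_tinnitus_index(
  gen_gap_trials(gt_bl, 10, 500, condition = "BL"),
  gen_gap_trials(gt_post, 10, 500, condition = "post-1"),
  gen_silence_trials(gt_bl, 10, 500, condition = "BL"),
  gen_silence_trials(gt_post, 10, 500, condition = "post-1"))
as.data.frame(ti)
#>   animal condition_pair m_cont m_thresh m_silence    TI
#> 1     F1   BL vs post-1 0.0551    0.208     0.159 0.423
```

All three metrics are positive — improved continuous-sound detection,
elevated gap thresholds, impaired silence detection — and the index sums
them: clear behavioural evidence for tinnitus in this simulated animal.
An unchanged animal gives TI ≈ 0.

ABR changes for the same kind of comparison (thresholds up 10 dB, response
growth reduced):

```r
abr_bl <- gen_abr(abr_ground_truth(seed = 1), condition = "BL")
abr_po <- gen_abr(abr_ground_truth(
  threshold_db = abr_bl$ground_truth$threshold_db + 10,
  growth_uv_per_db = 0.014, seed = 2), condition = "post-1")
abr_compare(abr_metrics(abr_bl), abr_metrics(abr_po))
#> $m_thresholds
#> $m_thresholds$elevation_db
#> [1] 14
#> $m_thresholds$literal_db
#> [1] -14
#>
#> $m_abr_magnitude
#> [1] -45.56341
```

A 14 dB mean threshold elevation and a 46% reduction in ABR magnitude:
evidence for hearing loss. `run_pipeline(run_config(seed = 1))` chains all
stages — behaviour, index, ABR, sleep spectra and evoked responses — on a
bundled synthetic scenario and writes tidy tables plus a JSON run manifest.

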