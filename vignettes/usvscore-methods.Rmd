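---
title: "Detection, parameterization and classification of rodent USVs with usvscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection, parameterization and classification of rodent USVs with usvscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usvscore)
```

## The problem

Rats vocalize in the ultrasonic range in two affectively distinct families:
22–28 kHz calls (long alarm calls and a short variant) and 50–55 kHz calls,
which appear as flat tones, frequency-modulated ramps and steps, and
sinusoidally modulated trills. Hand-scoring these calls from spectrograms is
slow (hours per few minutes of audio), requires trained scorers, and limits
experimental designs. usvscore automates the three stages of scoring —
detection, acoustic parameterization, and call-type classification — and
ships the evaluation machinery (detection sensitivity/precision against
hand-scored ground truth, per-class precision/recall/F1/support, Cohen's
kappa) plus a synthetic-USV generator so the whole pipeline is testable
without laboratory recordings.

The guiding assumptions of the detector are deliberately minimal, so that it
works across recording environments without per-site tuning:

1. most spectrogram time–frequency bins are background noise, and
2. calls are *connected* regions of time, frequency and acoustic power that
   stand out from that background.

## Spectrograms

`compute_spectrogram()` uses a periodic Hann window with 75% overlap and
expresses power in dB relative to a full-scale sinusoid, floored at
−120 dB. The analysis band defaults to 15–100 kHz, covering both call
families.

The default window is 256 samples at 250 kHz (≈1.02 ms, ≈977 Hz bins).
This is shorter than the ~2 ms window one might first reach for, and the
reason is trills: a trill with depth 6 kHz and rate 60 Hz sweeps at up to
$2\pi \cdot 6\,\mathrm{kHz} \cdot 60\,\mathrm{Hz} \approx 2.3$ MHz/s, so over
a 2 ms window the instantaneous frequency moves through ~9 bins and the ridge
loses ~10 dB to smearing — enough to push a 15-dB-SNR trill below any
reasonable threshold. At 1 ms the within-window sweep stays near one bin and
trilled calls are as bright as flat ones. The cost, ~1 kHz frequency
quantization, is handled downstream by sub-bin interpolation.

## Detection

`estimate_background()` models the noise per frequency bin by the median and
the scaled median absolute deviation of that bin's dB values over time, with
one sigma-clipping refinement: pixels more than 6 dB above the first-pass
median are excluded and the statistics recomputed. The refinement matters
when a call occupies a large share of its bin's frames — a raw MAD inflates
continuously with contamination, whereas after clipping the estimate stays at
the noise level for any call strong enough to be worth detecting.

`threshold_mask()` flags pixels above
`median + max(k_db, k_sigma * spread)` per bin. For Gaussian noise the
per-pixel linear power is exponential and its dB spread (scaled MAD) is
≈5 dB, so the defaults `k_db = 8`, `k_sigma = 2.5` put the threshold
≈12.4 dB above the per-bin median. That leaves a noise-pixel tail probability
of about $6\times10^{-6}$ (≈100 isolated pixels per minute of audio), which
the morphological and size gates remove, while staying below the 15 dB SNR of
the faintest calls the package is expected to find. A larger `k_sigma` (e.g.
4) would place the threshold near 20 dB and provably miss 15–18 dB calls.

`extract_components()` closes the mask morphologically (bridging gaps up to
3 ms × 2 kHz so briefly interrupted tonal tracks stay one component), labels
8-connected components, and keeps those at least 5 ms long with at least 12
above-threshold pixels. Components longer than 5 s are split at their widest
internal silent gap. `pad_and_coalesce()` then pads candidates by 5 ms on
both ends ("several milliseconds" to catch call onsets and tails) and merges
any time-overlapping candidates.

Broadband cage clicks — 1 ms transients — survive thresholding but fail the
5 ms duration gate, which is why the detector tolerates 10 clicks/min with
essentially no false positives.

## Isolation and detection confidence

`extract_ridge()` takes, per frame inside a candidate, the frequency of
maximal power (the call's *ridge*), marks frames whose ridge power clears the
detection threshold as valid, and refines the call bounds to the first and
last valid frames. An internal silent run longer than 12 ms (four times the
closing gap) splits the candidate into separate calls; shorter runs are kept
and reported as *gaps*. The 12 ms figure is deliberately above the 10 ms
silent breaks that stepped ("split") 50-kHz calls contain, so such calls stay
single calls with `n_gaps = 1`.

Detection confidence is a documented logistic map of ridge SNR, the only
property the underlying idea requires being monotonicity in signal power
relative to background:

$$\mathrm{confidence} = \frac{100}{1 + \exp(-(s - s_{0})/w)},$$

with $s$ the median over valid frames of ridge power minus the per-bin noise
median (dB), midpoint $s_0 = 10$ dB and scale $w = 3$ dB. A 10 dB call scores
50%, a 19 dB call ≈95%. `filter_by_confidence()` partitions calls at a
user-chosen threshold so low-confidence detections can be routed to manual
verification.

## Parameterization

`parameterize()` produces a fixed 49-field record per call
(`call_parameter_fields()`): duration; frequency statistics (max, min,
median, mean, SD, IQR, bandwidth, start/end, per-third means); ridge power
statistics (max with its frequency, min, median, mean, SD); slope statistics
(max, min, median, mean, SD in Hz/s) for the whole call and for its first,
middle and last thirds; jump and gap counts; slope variability; and slope
sign changes.

Two numerical choices matter here:

* **Sub-bin ridge interpolation and resampling for slopes.** With ~1 kHz bins
  and a 0.26 ms hop, raw per-hop frequency differences are degenerate (0 or
  ±3.8 MHz/s), so every slope statistic would be meaningless. The ridge is
  therefore refined by quadratic interpolation of the spectral peak across
  its two neighbouring bins, median-smoothed over 3 frames, and resampled to
  a ~2 ms grid before slopes are taken. A 200 kHz/s chirp is then recovered
  within a few percent, while trills (slopes swinging ±0.5–2 MHz/s) remain
  unmistakable.
* **Jumps are excluded from slope statistics.** An adjacent frequency change
  above 8 kHz counts as a jump (step calls), and removing it keeps the slope
  SD of a step call from being dominated by one artificial spike.

Thirds are assigned by valid-frame index (robust to gaps), with remainder
frames going to the first and middle blocks. Sign changes are counted only on
slopes above 200 kHz/s in magnitude; that floor sits several standard
deviations above the interpolation-noise slope level of a flat call
(~50–70 kHz/s mean absolute slope change) and far below trill slope
amplitudes, so flat calls count ~0 sign changes and trills count ≈2 per
modulation cycle.

## Classification

The five-call composite scheme collapses the 16 Wright-style call types into
`FixedFrequency50`, `FrequencyModulated50`, `FrequencyModulatedTrill50`,
`Long22kHz` (≥300 ms) and `Short22kHz` (`map_wright_to_composite()`).

Because no random-forest package is available in the target environment, the
package carries its own compact implementation (`rf_train()`): bagged CART
trees grown on bootstrap samples with Gini impurity, a random feature subset
per split, optional depth limit, inverse-frequency class weights (the
reference corpus ranges from 71 to 342 calls per class), mean-leaf-proportion
probabilities and impurity importance. All randomness flows from one integer
seed through a Mersenne-Twister stream in C++, so results are reproducible
across platforms.

The training protocol (`tune_and_train()`) mirrors standard practice:

* an unstratified seeded 70/30 split (`split_train_test()`; 931 calls give
  651 train / 280 test);
* feature selection on the training portion only: drop zero-variance fields,
  rank by impurity importance from a preliminary forest, keep at most 20;
* grid tuning by 5-fold cross-validation on the training portion over trees
  ∈ {100, 300}, depth ∈ {unlimited, 10, 20}, features-per-split ∈ {√p,
  0.3 p}; ties go to the smaller forest, then to grid order;
* refit of the winning configuration on the full training set.

Rows are put into a canonical order before folding so that the tuned
hyperparameters do not depend on how the caller happened to sort the training
table. Whether the original study stratified its split is unknown; the
unstratified default is the simpler assumption and the class counts are large
enough that folds stay populated.

The 22-kHz versus 50-kHz distinction is left entirely to learned features
(median frequency), not a hard rule — the classifier is a pure
machine-learning stage.

## The synthetic-USV generator

`random_recipe()`/`synthesize_recording()` build seeded recordings of
phase-continuous FM tones in white Gaussian noise with Poisson-placed 1 ms
broadband clicks. Defaults state the world the tests assume:

| quantity | default | why |
|---|---|---|
| sample rate | 250 kHz | typical rat USV hardware (192–300 kHz) |
| noise floor | −40 dBFS RMS | keeps 16-bit export clean, far above the −120 dB floor |
| per-call SNR | uniform 15–25 dB | "clearly visible to a scorer" down to "faint but real" |
| clicks | 10/min, 1 ms, +20 dB | cage-noise transients that plague USV detectors |
| FixedFrequency50 | f0 45–65 kHz, 20–150 ms, drift ≤1.5 kHz | flat/short Wright types |
| FrequencyModulated50 | sweep 8–18 kHz (ramp, 2–3-plateau step, or inverted-U), 30–200 ms | ramp/step/complex types |
| FrequencyModulatedTrill50 | depth 3–6 kHz, rate 30–60 Hz, 80–250 ms | sinusoidal trills |
| Long22kHz | 22–27 kHz, 0.35–1.2 s | alarm calls (≥300 ms by definition) |
| Short22kHz | 22–27 kHz, 50–250 ms | short variant |
| call spacing | ≥50 ms, onsets uniform | isolated calls, no bout structure |
| edge ramps | 2 ms raised cosine | fast onsets; keeps the annotated duration recoverable to a few ms |

SNR is specified in the spectrogram domain (ridge power over the per-bin
noise median); the generator converts it to a linear amplitude via the Hann
tone calibration $10\log_{10}(N/(6\ln 2)) \approx 17.9$ dB for the default
256-sample window.

What the generator does *not* emulate — and therefore what a green test does
not establish — includes: bout structure and inter-call dependencies,
reverberation and non-stationary or narrowband interference, overlapping
simultaneous callers, amplitude modulation within calls, harmonics, and the
soft boundaries between call types that make real hand-scoring ambiguous. The
synthetic classes are separable by construction, so classifier accuracy on
synthetic data (well above 0.9 in the packaged tests) is a floor-check of the
pipeline's plumbing, not an estimate of real-data accuracy (≈0.79 against an
expert scorer is the published reference point for this kind of corpus).

## Evaluation

`match_calls()` pairs predicted with ground-truth intervals greedily,
one-to-one, by descending temporal overlap (any positive overlap qualifies;
ties by earlier start). A midpoint-distance policy with a 30 ms tolerance is
available as an alternative; one-to-one matching is enforced in both.
Sensitivity is Detected/(Detected+Missed) and precision
Detected/(Detected+False Positives). `metrics_table()` implements the
standard per-class one-vs-rest precision/recall/F1/support with multi-class
accuracy $\sum_c \mathrm{TP}_c / n$; a class never predicted reports
precision 0 with a flag rather than dropping its row. `cohens_kappa()` and a
pooled two-proportion z-test (the conventional test for comparing two
detection rates; the original analysis does not name its test) round out the
toolkit.

## Hand-scorer training sessions

`training_session()` replays the immediate-feedback trainer headlessly: an
expert key, one attempt record per answer, retry-until-correct semantics, and
`first_attempt_accuracy()` at completion. A trainee answering uniformly at
random scores ≈20% on first attempts — the five-class chance level — while an
agent that mirrors the key scores 100%; reliability between scorers is then
quantified with `cohens_kappa()` on their results CSVs.

## Known limitations

* The detector assumes stationary broadband noise per bin; slowly drifting
  noise floors are absorbed by the per-bin statistics, but strong
  *narrowband* interference (a persistent tone) will occupy a bin's median
  and suppress detection in that bin.
* Recordings are rejected, not resampled, when the rate is below Nyquist for
  the analysis band; resampling is out of scope.
* Call bounds are refined to threshold crossings, so measured durations sit
  a few milliseconds inside the annotated onsets/offsets (edge ramps).
* The confidence score is a calibrated-by-design logistic map, not a
  probability estimated from data.
* Overlapping simultaneous calls in the same time window are coalesced into
  one candidate; the generator flags but does not prevent overlaps when asked
  to place them.
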