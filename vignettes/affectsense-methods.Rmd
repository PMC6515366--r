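---
title: "Methods: biosignal emotion recognition and emotion-aware activity recommendation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biosignal emotion recognition and emotion-aware activity recommendation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectsense)
```

## Overview

`affectsense` implements, end to end and at desk scale, an affective-computing
stack of the kind used in wearable assistants for elderly care: synthetic
ECG/PPG/EDA acquisition through a low-cost sensing chain, powerline-noise
removal, extraction of the six classic per-channel statistics, a fully
connected 18-input / 7-emotion classifier, and a health-profile-aware
activity recommender that learns user preferences from accept/deny feedback.
Because no public recording set accompanies this design (the common corpora
are licensed), the package's own simulator is the canonical data source, and
all headline behaviour is validated as *parameter recovery*: the simulator
plants class-dependent physiology, and the pipeline must recover the classes
on held-out recordings.

## The forward sensing model

Each simulated recording has three channels sampled uniformly at
`sampling_rate_hz` (default 250 Hz) for `duration_s` (default 10 s):

* **ECG** — a sum-of-Gaussians PQRST template repeated at beat times whose
  intervals are `60 / heart_rate_bpm` seconds with relative Gaussian jitter
  `hr_variability`. The waveform sits at the amplifier's mid-rail (1.65 V)
  with an R-peak excursion of about 0.95 V, emulating an instrumentation
  amplifier driven to a 3.3 V rail. A template train is used rather than a
  biophysical model because the downstream pipeline consumes only aggregate
  statistics; spectral and statistical realism suffice.
* **PPG** — per beat, a systolic Gaussian pulse plus a smaller, delayed
  dicrotic wave, amplitude `ppg_amplitude` volts, sharing the ECG's beat
  train as the two signals do physiologically.
* **EDA** — skin *resistance* is modelled as a slowly drifting tonic level
  (`eda_tonic_level_ohms`, mega-ohm order for dry skin) plus phasic
  skin-conductance responses arriving as a Poisson process at
  `eda_scr_rate_per_min`, each with a fast (~0.75 s) rise and slow (~3 s)
  exponential decay, combined on the conductance scale. The resistance is
  then read through the measurement circuit actually used by low-cost
  harnesses: a voltage divider with series resistor `divider_r1_ohms`
  (default 500 kΩ) polarised at `vref_volts` (default 3.3 V), so the
  digitised quantity is `v = vref · R1 / (R1 + R_skin)`.

Two contaminants are added to every channel: a mains sinusoid at
`mains_freq_hz` (default 50 Hz, amplitude `mains_amplitude`, default 0.05 V —
clearly visible but not dominant, as typical of chest-strap recordings) and
broadband white noise of standard deviation `motion_artifact_level` (default
0.01 V) standing in for EMG/motion pickup. Finally the signal passes a
12-bit ADC model: clipping to `[0, vref]` (real converters saturate) and
rounding to the nearest multiple of `vref / 2^adc_bits` ≈ 0.0008 V. The
config requires `sampling_rate_hz > 2 · mains_freq_hz`, otherwise the
contaminant the filter exists to remove would not be representable.

### Class-dependent physiology

The seven emotion classes shift five generator parameters
(`default_emotion_params()`): sympathetic arousal (fear, anger, surprise)
raises heart rate and SCR rate and lowers tonic skin resistance; sadness
does the opposite; happiness and disgust sit between. The values are chosen
once to be *separable but overlapping* — adjacent classes differ by amounts
comparable to the within-class jitter, so classification is non-trivial but
learnable. These shifts are a synthetic stand-in for real stimulus-response
physiology: passing the recovery tests shows the pipeline recovers planted
class structure, not that it would reach any particular accuracy on human
recordings, whose class overlap is far larger and whose artifacts
(electrode movement, baseline wander, missing beats) the simulator does not
model.

## Preprocessing

Mains interference is removed with a 3rd-order Butterworth band-stop filter,
48–52 Hz by default. The design is delegated to `signal::butter`; the
application and response evaluation are this package's own, with the
conventions pinned down so results are reproducible bit for bit:

* **Zero phase.** The filter is run forward and backward (processing is
  offline), which squares the magnitude response and cancels the phase.
* **Edges.** The signal is extended by odd reflection over `3 · order`
  samples at each end, and each pass starts from the steady state of a step
  at the first sample (so constants map to themselves to machine precision).
* **Transients.** A narrow notch necessarily rings near the recording edges:
  its poles sit at radius ≈ 0.975, giving a transient of roughly a hundred
  samples that no padding convention can remove. Attenuation contracts are
  therefore stated and tested on probe tones long enough (minutes) that the
  edge transient contributes negligibly to the whole-signal RMS; on a 10 s
  recording the interior is equally clean but the edge samples are not.

`filter_response()` evaluates `20·log10|H|` directly from the coefficients;
tests cross-check it against an independent polynomial evaluation and assert
≥ 40 dB stopband attenuation at 50 Hz and a passband flat to 0.5 dB.

## The six statistics and the 18-dimensional input

Per channel, with samples `X_1..X_N` (N ≥ 3):

| statistic | definition |
|---|---|
| `mean` | `Σ X_n / N` |
| `std`  | sample standard deviation, `1/(N−1)` normalisation |
| `afd`  | `Σ |X_{n+1} − X_n| / (N−1)` on raw samples |
| `afdn` | the same on z-normalised samples |
| `asd`  | `Σ |X_{n+2} − X_n| / (N−2)` on raw samples |
| `asdn` | the same on z-normalised samples |

The normalised variants use the same sample standard deviation as `std`,
for internal consistency. One vector per recording is produced (no
sub-windowing), in the fixed order ECG(6), PPG(6), EDA(6); assembly is by
declared channel kind, never by argument position. Features are computed on
the filtered signal by default — cleaning precedes extraction in the sensing
chain — with `filtered = FALSE` available as a switch.

A constant channel makes the normalised differences undefined; this is
raised as a distinct degenerate-signal condition rather than silently
returning `NaN`, with `partial = TRUE` available to obtain the four defined
statistics.

## The classifier

A fully connected network with hidden stack 32–64–128–64–32 (ReLU), softmax
over the seven labels, trained with mean squared error against one-hot
targets (cross-entropy is a non-default option). Regularisation follows the
configured dropout (0.2 on hidden activations, training only) and L2
penalty (0.01).

Numerical choices that required a decision:

* **L2 as decoupled weight decay.** Folding the L2 gradient `2λW` into the
  adaptively rescaled Adam update lets the decay direction dominate the
  small per-entry MSE gradient: the network verifiably collapses to the
  uniform predictor (training MSE converges to `6/49` and stays there).
  The penalty is therefore applied in the AdamW convention — subtracted
  directly in the update step as `lr · 2λ · W` — which regularises the
  weights without interacting with the gradient normalisation.
* **Early stopping** monitors the validation loss with `min_delta = 1e-3`
  and patience 20, keeping the weights of the best epoch. A min-delta of
  10 is representable in the configuration but meaningless for a loss
  bounded by 1, and is not the default.
* **Optimiser defaults** (Adam, learning rate 1e-3, batch 32, max 300
  epochs) are ordinary choices for a problem of this size and are all
  recorded in `model_config()`.
* **Standardisation.** Inputs are standardised with training-set means and
  standard deviations (stored in the model); the raw features span volts to
  dimensionless ratios and differ by orders of magnitude.
* **Determinism.** All randomness (initialisation, shuffling, dropout)
  derives from `config$seed`; inference disables dropout, so prediction is
  a pure function of the weights.

The 80/10/10 split draws a seeded random permutation; test and validation
get `round(0.1 · n)` recordings each and training absorbs the rounding
remainder, so n = 100 gives exactly 80/10/10 and n = 10 gives 8/1/1.

The default recovery experiment — 7 classes × 60 recordings at the simulator
defaults, seed 1 — is the package's acceptance condition: held-out accuracy
of at least 0.90, computed end to end (simulate → filter → featurise →
split → train → evaluate) in well under five minutes on one CPU. Problem
sizes in the unit tests are smaller (a few classes, a few recordings,
2–6 s durations) purely to keep the suite fast; the full experiment lives in
the acceptance tests.

## The recommender

Activities rate their impact per feature (shoulders, arms, column, legs,
feet, cognitive load, dangerous tools) on the ordinal scale
none < light < mild < hard; profiles record the maximum impact the user may
safely receive per feature. Compatibility of one rating pair is 1 when the
impact is within tolerance and otherwise falls linearly with the ordinal gap
(`1 − gap/3`); `dangerous_tools` is all-or-nothing, since partial credit for
unsafe tool use is not meaningful. The score is

```
score = Σ_f  w_f · compat_f  +  s · preference(activity)
```

with equal weights `w_f` summing to the feature cap (0.9) and preference
share `s = 0.1`; the two always sum to 1. A fully compatible activity with
zero preference scores exactly 0.9 — the configuration's structural maximum
for the health component, reported by the acceptance script.

Decisions where the design was genuinely open:

* **Close fit** is defined as a health-feature component of at least
  `close_fit_min_score` (default 0.7, i.e. ~78% of the attainable 0.9): the
  threshold above which a denial is "abnormal" enough to count toward the
  caregiver trigger. Denials of poorly fitting activities never count.
* **The 7-denial counter** counts *consecutive* close-fit denials and
  resets on any acceptance, reflecting its role as an abnormal-behaviour
  detector rather than a lifetime tally. On the 7th the configuration is
  reweighted — 0.05 moves from the feature cap to the preference share,
  feature weights are rescaled proportionally — the counter resets, and a
  caregiver notification is logged. Repeated runs of denials re-trigger it.
* **Learning step** δ = 0.05 per accept/deny (clipped to [0, 1]) makes the
  7-denial dynamics and preference saturation visible within short
  simulations; both δ and the reweight step are per-user configurable.
* **Emotion policy.** High-intensity activities are emotional boosters,
  low-intensity ones de-stressers. The label mapping is: Sad and Neutral →
  booster; Angry, Afraid, Disgusted → de-stresser; Happy and Surprised →
  no filter. When the filter empties the catalog the recommender falls back
  to the unfiltered ranking and flags it, rather than failing.
* **Ties** break towards the higher preference weight, then the
  lexicographically smaller id, making recommendations fully deterministic.
* **Preference** is a per-user, per-activity scalar in [0, 1]; nothing more
  structured is warranted by the feedback signal (one bit per suggestion).

Scheduling is earliest-fit into the user's free slots, shrinking the chosen
slot; absence of a sufficient slot is a signal, not an error. Acceptance of
a suggestion is taken as execution — no activity verification is modelled.

## Degenerate inputs and numerical conventions

* Signals shorter than 3 samples are rejected everywhere (the second
  difference needs them); signals shorter than `3 · order` samples cannot
  be reflect-padded and are rejected by the filter.
* ADC behaviour on out-of-range samples is clipping, not error, mirroring
  hardware saturation; quantization is idempotent and its per-sample error
  is bounded by half a step.
* Probability vectors must sum to 1 within 1e-6; z-normalisation must hit
  mean 0 / sd 1 within 1e-9; the feature implementations must agree with a
  loop-based brute force within 1e-12.
* Per-recording seeds are derived as `seed + 7919·i (mod 2^31 − 1)` so
  datasets are reproducible while recordings stay mutually independent.

## Known limitations

* The simulator's class-conditional parameters are a declared stand-in, not
  estimates from human data; recovery results bound nothing about clinical
  performance.
* Motion artifact is white noise; real EMG contamination is coloured and
  transient, and real PPG motion artifact is correlated with the pulse.
* One feature vector per recording: no windowing, no HRV or spectral
  features.
* The band-stop filter's edge transient means the first/last ~0.5 s of a
  filtered recording are not fully cleaned; at the default 10 s duration
  this is part of the feature noise floor.
* The recommender's catalog fixture is illustrative; impact ratings for a
  real deployment would come from clinical guidance.
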