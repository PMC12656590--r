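---
title: "Methods: spectral AF detection from multi-site BCG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral AF detection from multi-site BCG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the model and of the design
choices made where the analysis left room for them. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The signal model and its assumptions

A bed-sensor ballistocardiogram in the supine position superimposes three
components on a large ADC offset: (i) a train of heartbeat-induced
vibrations, one transient per cardiac ejection; (ii) a slow respiratory
oscillation; (iii) broadband sensor noise, punctuated by large body-motion
artifacts. The detection principle is purely spectral: over a 32.768 s
block, a near-periodic beat train at rate $f_0$ concentrates power at
$f_0, 2f_0, 3f_0, \dots$ (the harmonic comb, prominent below ~10 Hz),
whereas the irregularly irregular intervals of atrial fibrillation spread
that power and the comb disappears. Classification therefore never needs
beat detection, RR extraction, or filtering — only the windowed power
spectrum of the standardized block. The assumptions inherited from this
model are that the participant is at rest and supine, that heart rate is
quasi-stationary within a block, and that motion artifacts are sparse
enough to be excised block-wise.

## The synthetic cohort generator

No public corpus of labelled multi-site BCG exists, so the package
generates one with exactly the structure the analysis relies on. Its
defaults are fixed study conditions, not tuning knobs.

* **Beat grid.** Sinus RR intervals are normal with mean $60/\mathrm{HR}$
  and coefficient of variation 0.03, truncated below at 0.2 s (a
  physiological refractory floor); AF intervals are i.i.d. log-normal with
  CV 0.24. The AF model is deliberately minimal: independent high-CV
  intervals are sufficient to destroy the comb, which is the only property
  the classifier uses.
* **Beat morphology.** Each beat contributes a damped sinusoid
  $e^{-t/\tau}\sin(2\pi f_c t)$ with $f_c = 5$ Hz and $\tau = 0.15$ s,
  mean-subtracted so the cardiac component is zero-DC. The kernel is a
  parsimonious stand-in for true BCG morphology (which is strongly
  device-dependent); what matters downstream is that a periodic impulse
  train convolved with *any* fixed kernel yields the harmonic comb.
* **Placement profiles.** Cardiac gain peaks at the chest-level sensor
  (BCG2: 800 counts, vs 400/250/150 at 0/45/65 cm from the head);
  respiratory gain is relatively largest at the lumbar/sacral sensors
  (150 counts vs 60–80). This encodes the qualitative anatomy — the chest
  sensor sits at heart level, the caudal sensors near the organs that move
  with breathing — and makes the head-direction sensor a near neighbour of
  the chest profile while the caudal sensors are poorer, reproducing the
  observed cross-location asymmetry.
* **Amplitude scale.** DC offset 32,800 counts with white noise SD 20;
  clean per-block means stay within ±50 counts of the 32,794-count anchor
  and clean maxima stay below the 34,000-count gate, so only injected
  artifacts are excluded. Heart rates are per-participant draws from
  label-specific normals (AF 70 ± 10, sinus 64 ± 14 bpm, truncated to
  40–120), matching the cohort demographics the simulation emulates.
* **Artifacts.** Bursts arrive as a Poisson process at 0.5/min per channel
  (independently across channels, as real repositioning loads sensors
  unevenly), last 0.5–2 s, and add a 6,000-count half-sine, so every burst
  exceeds 34,000 raw counts by construction. The rate yields single-sensor
  inclusion fractions around 70–80% on 5-minute recordings, in the
  realistic range for bed recordings, and leaves room for fusion to
  recover blocks.
* **Reproducibility.** All randomness flows from one master seed;
  per-participant and per-channel sub-streams are derived arithmetically,
  so cohorts are bit-identical across runs and platforms.

What the generator does **not** emulate: posture changes and non-supine
positions, beat-morphology variability within a participant, sensor
cross-talk, paroxysmal (intermittent) AF within a recording, and ectopy in
sinus rhythm. Passing tests on synthetic cohorts therefore demonstrate
that the pipeline is correct and that the spectral mechanism separates the
rhythm classes under the stated model — not that clinical accuracy will
match; the synthetic classes are cleanly separated by design, and measured
accuracies sit near the ceiling.

## Preprocessing conventions

Fixed numerical choices, each needed for exact reproducibility:

* Block length 16,384 samples = 32.768 s × 500 Hz and stride 2,048 samples
  = 4.096 s — powers of two, which is why the spectrum of one block has
  exactly $16384/2 + 1 = 8193$ points over 0–250 Hz. A trailing partial
  window is dropped; the block count is $\lfloor (N-L)/S \rfloor + 1$.
* Standardization uses the population SD (divisor $N$). A zero-variance
  block raises a degenerate-block error and is excluded by callers.
* The noise statistic is the per-block **maximum** amplitude (raw or
  standardized); only an upper threshold is applied, since motion loads
  the piezo sheet upward. The standardized-threshold calibration returns
  the $(m{+}1)$-th largest statistic for a target of $m$ exclusions, so
  ties break toward excluding fewer blocks and the round-trip count is
  exact.
* The spectrum is $|X_k|^2/N$ after a pointwise Hanning window, with no
  window-gain compensation — classifiers see consistently scaled features,
  so a global factor is irrelevant.
* Cropping keeps $f_{\text{low}} \le f \le f_{\text{high}}$ with both ends
  closed (a low cut of 0 keeps the DC point). Binning partitions the
  cropped range into equal-width intervals and **sums** power within each
  (the last interval closed). Sum rather than mean aggregation was chosen
  so total binned power equals total cropped power and the single-bin case
  reads as band power; with equal-width bins the two differ only by a
  constant per bin and are equivalent for the classifiers.

## Classifier tuning

The four families and their tuned grids: decision tree (depth 1–15),
random forest (depth 1–40, 100 trees, depth mapped to a `maxnodes` cap of
$2^{\text{depth}}$), L2 logistic regression ($C$ from $10^{-8}$ to
$10^{8}$; implemented as ridge with $\lambda = 1/(Cn)$, the standard
correspondence between the inverse-regularization and penalty-scale
parameterizations, without feature standardization), and AdaBoost over
depth-limited trees (depth 1–8, learning rate 0.8–1.0). AdaBoost is
implemented in-package as SAMME with learning-rate shrinkage of the stage
weights $\alpha_m = \eta \log\frac{1-\epsilon_m}{\epsilon_m}$, 50
estimators, stopping early on a perfect or chance-level learner; its score
is the $\alpha$-weighted vote share for AF. Untouched hyperparameters are
frozen at the underlying libraries' defaults and recorded in the run
manifest.

Validation is grouped by participant: folds partition participants, never
blocks, so within-subject correlation cannot leak across the split.
Stratification deals AF participants round-robin across folds, then fills
with non-AF participants greedily onto the smallest folds — every fold's
AF count is within one participant of balance. Grid search maximizes mean
fold accuracy; ties break toward the earliest configuration in the
deterministic grid order (family, then hyperparameters, then setting).
Leave-one-participant-out CV reports the per-participant block accuracy
and its mean ± SD. The full joint grid (160 settings × 49 hyperparameter
points) is exposed via `default_grid()`; the shipped `reduced_grid()`
covers the winning neighbourhood (AdaBoost around 0–10 Hz/30 bins, one
representative per other family) so an end-to-end run stays at desk scale.

## Fusion semantics

Channels are recorded simultaneously, so blocks align exactly by
`(participant_id, start_sample)`. For a sensor subset $S$, a block's fused
label is AF iff any sensor in $S$ with a noise-passing window predicts AF,
and the block is excluded only when **no** sensor in $S$ has a prediction.
This "OR over available" reading is forced by the inclusion arithmetic: a
combination can only retain more blocks than its best single sensor if
partially noisy blocks survive through their clean channels. Consequences,
verified exhaustively over all $2^4$ per-block vote patterns: on the
common (all-available) block subset, fused recall dominates every
component's recall and fused specificity is dominated by every component's
specificity; inclusion counts are monotone in the subset lattice. The
inclusion percentage is reported against the cohort's total aligned block
count.

## Problem sizes and runtime

The default end-to-end configuration simulates the full study design — 67
training/validation participants (23 AF / 44 non-AF) and 17 test
participants (6 AF / 11 non-AF), 300 s four-channel recordings, 66 blocks
per channel — and completes in roughly two minutes on one CPU with the
reduced grid; spectra are stored only up to 40 Hz (the highest cutoff the
reduced grid uses) to bound memory. Unit tests run on 65.536 s recordings
(9 blocks per channel) except where the study-scale properties themselves
are under test.

## Known limitations

* Evaluation is block-level; participant-level screening decisions would
  need an aggregation rule (e.g. a minimum fraction of AF blocks) that is
  out of scope here.
* The AUC of the OR-fused decision uses the maximum available per-sensor
  score as a fused score; only the label-level metrics are contractual.
* Reported metric tables round half away from zero to two decimals
  (`format_report()`); all internal computation is full precision.
* The generator's separability places tuned models near ceiling accuracy,
  so comparative statements between configurations on synthetic data have
  limited resolution.
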