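---
title: "Estimating cardiac filling pressure class from wrist PPG morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cardiac filling pressure class from wrist PPG morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pulmonary capillary wedge pressure (PCWP) is the reference measure of
left-sided filling pressure and congestion in heart failure, but it
requires a pulmonary-artery catheter. Wrist photoplethysmography (PPG)
is ubiquitous in wearables: every cardiac cycle produces one pulse wave
whose shape carries information about the arterial tree and, plausibly,
about filling state. `pulsewedge` implements a complete, reproducible
pipeline for asking whether pulse-wave morphology can classify subjects
into clinically meaningful PCWP categories (below vs. at or above
12 mmHg), in the setting where this question is typically studied: a
small catheterisation cohort with one PCWP value and one usable PPG
window per subject.

The package has five layers:

1. **Synthetic cohorts** (`generate_cohort()`) — PPG waveforms with
   known ground-truth morphology, rhythm, noise, and a tunable coupling
   between PCWP class and waveform shape.
2. **Preprocessing** (`select_window()`, `bandpass()`,
   `trim_transient()`) — selection of a 70-s window preceding the
   pressure measurement, zero-phase 2nd-order Butterworth band-pass at
   1–5 Hz, and removal of the first 10 s, leaving 60 s for analysis.
3. **Beats and features** (`detect_systolic_peaks()`,
   `locate_foot_and_diastolic()`, `extract_features()`) — fiducial
   points and six per-subject features: heart rate (HR), heart-rate
   variability (HRV), systolic amplitude (SA), diastolic amplitude (DA),
   crest time (CT), and a large-artery stiffness index (LASI).
4. **Models** (`crossval_regression()`, `crossval_lda()`,
   `roc_curve()`) — single-feature linear regression of the continuous
   pressure and single-feature linear discriminant classification of the
   pressure class, both with three-fold cross-validation and pooled
   out-of-fold metrics.
5. **Group statistics** (`mann_whitney_u()`, `bonferroni_alpha()`,
   `compare_features()`) — non-parametric comparison of each feature
   between classes with Bonferroni correction.

## Features and their definitions

Let the filtered signal be $y(t)$ and, for beat $k$, let $f_k$, $s_k$,
$d_k$ be the foot, systolic-peak and diastolic-peak times. The per-beat
quantities are

* $\mathrm{SA}_k = y(s_k) - y(f_k)$ and
  $\mathrm{DA}_k = y(d_k) - y(f_k)$ (amplitudes in device units);
* $\mathrm{CT}_k = s_k - f_k$ (crest time, s);
* $\Delta T_k = d_k - s_k$ and $\mathrm{LASI}_k = 1/\Delta T_k$
  (1/s) — a stiffer arterial tree reflects the pulse earlier, giving a
  shorter systolic-to-diastolic delay and a larger index;
* $\mathrm{IBI}_k = s_{k+1} - s_k$, from which
  $\mathrm{HR} = 60/\overline{\mathrm{IBI}}$ and
  $\mathrm{HRV} = \mathrm{SDNN}(\mathrm{IBI})$.

Several of these definitions are genuinely open choices, exposed in the
configuration and resolved as follows:

* **LASI form.** The classical stiffness index is body height divided by
  $\Delta T$; height is unavailable from a wrist wearable, so the
  reciprocal delay is used, which preserves the "stiffer → larger"
  reading. $\Delta T$ itself is reported alongside (`delta_t_s`).
* **HRV metric.** SDNN over the 60-s window (RMSSD available via
  configuration); SDNN is the common short-window choice.
* **Aggregation.** Per-subject values are the *median* over
  quality-passing beats (mean available), for robustness to residual
  artifacts.
* **Foot definition.** The signal minimum between consecutive systolic
  peaks. The tangent-intersection onset is deliberately out of scope:
  the inter-peak minimum is simpler and stable on band-passed signals.

## Preprocessing decisions

**Zero-phase filtering.** The Butterworth band-pass is applied forward
and backward (`signal::filtfilt`). The timing features (CT, $\Delta T$)
would be biased by the group delay of a causal filter; zero-phase
filtering removes that bias at the cost of non-causality, which is
irrelevant offline. The effective magnitude response is then the
*squared* single-pass response $|H(f)|^2$: a component at the 1-Hz or
5-Hz design edge is attenuated to half power twice, i.e. to 50% in
amplitude. All filter contracts in the test-suite are asserted against
this squared-response convention, computed independently from the
transfer function.

**Artifact screening.** The reference practice this pipeline mirrors is
*visual* screening with the window advanced (earlier) until a clean
70-s stretch is found, by at most 5 min. The default automatic stand-in
flags any candidate whose 1-s amplitude range exceeds 5× the window
median (burst) or falls below 1% of it (dropout/flat-line), searching in
10-s steps. The detector is a pluggable predicate, so a different
screening rule — or a human decision — can be substituted without
touching the window search.

**Sub-sample fiducials.** At 128 Hz one sample is 7.8 ms, which is 2% of
a 0.37-s crest time — the whole error budget for morphology recovery.
All fiducial positions are therefore refined by parabolic (three-point)
interpolation before conversion to seconds; amplitudes are read at the
integer sample.

## The classifier and the evaluation conventions

The classifier is one-dimensional two-class LDA: class-conditional
normals with pooled within-class variance and, by default, equal priors
(the validation cohorts are built with 50% prevalence; empirical priors
are a configuration option). Its discriminant is monotone in the
feature, so the model is essentially a learned threshold with a
probabilistic score.

* **Pooled out-of-fold metrics.** With 14 subjects and 3 folds, per-fold
  ROC curves are too unstable to average; instead the out-of-fold
  posterior scores of all subjects are pooled into one ROC (and one
  $R^2$). Scores are expressed as the posterior probability of the high
  class so that scores from different folds share an orientation.
* **Negative $R^2$.** Out-of-fold $R^2$ is
  $1 - \mathrm{SS}_{\mathrm{res}}/\mathrm{SS}_{\mathrm{tot}}$ with
  $\mathrm{SS}_{\mathrm{tot}}$ about the full-sample mean. An
  uninformative predictor *overfits* within each training fold and
  reliably underperforms the mean out of fold, so this convention admits
  — and under the null typically produces — negative values. This is
  deliberate: it reproduces the behaviour expected of single-feature
  regressions on a small cohort.
* **Stratified folds.** Fold assignment is stratified by class with a
  recorded seed; with 7 subjects per class, unstratified folds can lose
  a class entirely.
* **AUC and the rank test.** `roc_curve()` computes the area both by
  trapezoid over operating points and as the normalised Mann–Whitney
  U statistic with average-rank (midpoint) tie handling; the two agree
  to machine precision, and the identity $U/(n_1 n_0) = \mathrm{AUC}$ is
  exercised across modules in the tests.
* **Mann–Whitney p-values** are exact (via the null permutation
  distribution) when the smaller group has at most 8 observations and
  the data are untied, and use the tie-corrected normal approximation
  otherwise. The Bonferroni family defaults to the three morphology
  comparisons (SA, LASI, CT), giving the corrected level
  $0.05/3 = 0.0167$; the family size is a parameter rather than a
  hard-wired constant.

## The synthetic cohort generator

The generator exists to give the pipeline inputs with *known* truth; it
is first-class, tested code. Each beat is the sum of two Gaussian waves

$$ y(t) = A_s e^{-(t-c)^2/2w_s^2} + A_d e^{-(t-c-\delta)^2/2w_d^2}, $$

which is the minimal model giving independent control of all four
morphology features: $A_s \to$ SA, $A_d \to$ DA, $c \to$ CT,
$1/\delta \to$ LASI. Beats are concatenated on a continuous time axis
(no cumulative rounding), then sinusoidal baseline wander, white sensor
noise and optional high-amplitude artifact bursts are added. All
randomness flows from one explicit seed; identical seeds give
bit-identical cohorts.

**Default morphology.** The defaults emulate the population in which
simultaneous PPG/catheter data are collected: elderly patients with
severe aortic stenosis. Their pulse is slow-rising with a smoothed
dicrotic notch (*pulsus parvus et tardus*), hence a long crest time
(0.37 s), a broad systolic wave (width 0.18 s), and a modest, late
reflection wave ($A_d = 0.25$, $\delta = 0.44$ s, width 0.11 s). These
values were fixed once, by requiring that the full chain (band-pass →
fiducials → features) recover the template's truth on clean recordings:
the 1-Hz filter edge sits directly on the fundamental of a 60-bpm beat
train, and much of the template space is *not* recoverable through it —
narrow waves ring, widely separated reflection waves acquire artificial
prominence, and short diastolic gaps swallow the reflection wave
entirely. The chosen geometry recovers HR within 0.1% and CT/LASI
within about 1%.

**Rhythm.** Sinus subjects draw i.i.d. Gaussian inter-beat intervals
(SD 0.03 s) around a subject-level mean rate drawn from a narrow band
around 60 bpm (SD 0.8, clipped to 58–62). The band is deliberately
narrow for two reasons: the class signal should be carried by
morphology, not rate; and the measurement chain's timing biases drift by
roughly 1.5% per bpm away from 60, so a wide rate band would inject
rate-correlated noise into the timing features. Each subject's rate is
additionally capped so that the template fits into essentially every
drawn interval and the diastolic peak stays inside the locator's
half-interval search window.

**Atrial-fibrillation mode** draws intervals i.i.d. uniform over the
mean ±35%, floored at the template's minimum renderable interval so a
short diastole never clips the reflection wave's centre. This is not an
electrophysiological model; it produces the extreme, serially
uncorrelated HRV characteristic of AF. AF subjects also stress the
detector's regular-rhythm assumptions (long irregular gaps can provoke
spurious detections), pushing their features to the edge of their
class's distribution — qualitatively the behaviour reported for AF
patients in small PPG cohorts. AF is off by default in cohorts
(`af_rate = 0`) and enabled explicitly when wanted.

**Class coupling.** Pressures are drawn uniformly within each class's
range (low: 4–11.9 mmHg, high: 12–20 mmHg, prevalence 50%, mirroring a
7/7 catheterisation cohort). `effect_size` shifts the high class's mean
template by that many *between-subject standard deviations* (SA down,
CT up, delay down — directions chosen only to create separability, not
as physiological claims; no direction is established in the clinical
literature). `effect_size = 0` makes the classes exchangeable, which is
the basis of the null-calibration tests. By default there is *no*
continuous dose–response between pressure and morphology within a class
— classification can succeed while exact pressure regression fails,
which is precisely the qualitative regime of interest; a linear link
(`pcwp_link = "linear"`) exists for testing regression recovery.

## What the synthetic validation does and does not show

Passing the suite shows that the pipeline is *internally correct*: it
recovers known morphology through the specified filter, its AUC equals
the rank statistic it should equal, its cross-validation is calibrated
at chance under the null (mean pooled AUC 0.45–0.55 with no coupling;
median out-of-fold $R^2 < 0$), and it detects strong class-morphology
coupling at high AUC from raw waveforms at $n = 14$.

It does not show that real wrist PPG predicts PCWP. The generator's
beats are smooth two-Gaussian pulses; real PPG has richer harmonic
content, motion artifacts beyond burst noise, respiratory amplitude
modulation, and between-subject shape variation far beyond four jittered
parameters. The class-morphology directions are conventions. Rate and
morphology are independent here but are not in patients.

## Numerical choices and degenerate inputs

* Peak detection: local maxima with prominence ≥ 0.3 × the median
  per-second peak-to-trough range and separation ≥ 0.33 s (≈180 bpm
  cap); the taller of two close candidates wins. The prominence floor is
  what rejects reflection waves; detection fails with a classed error
  below 2 detected beats.
* Diastolic search: highest local maximum within half an inter-beat
  interval after the systolic peak, requiring prominence ≥ 5% of the
  beat amplitude so that sub-percent noise ripples on the systolic
  decay — which sit *higher* on the slope than the true reflection
  wave — are never selected. If no such maximum exists, the flattest
  point of the decay (first-derivative maximum between curvature zero
  crossings) serves as the shoulder estimate; beats with neither are
  kept but marked `quality_ok = FALSE` and excluded from morphology
  aggregation. A subject whose beats all lack a diastolic fiducial gets
  `NA` for DA and LASI and is excluded from those features' models only.
* Windows are half-open `[start, end)`; timestamps are seconds from
  recording start; a 70-s window at 128 Hz trims to exactly 7680
  samples.
* Constant features raise a degenerate-fit error; a training fold that
  would lose a class raises a stratification error (impossible with ≥3
  subjects per class and stratified assignment).
* Crest time through the full chain shows a mild compression toward the
  cohort mean (the detected foot is the *filtered* trough, whose
  position is partly set by the inter-beat gap geometry); this is a
  known, documented bias of the foot convention on band-passed signals,
  visible in the cohort-tracking test tolerances.

## Validation problem sizes

The shipped validation uses: 70-s recordings at 128 Hz (60 beats);
14-subject cohorts (7/7) for the end-to-end classification checks,
averaged over 10 generator seeds; 200-subject ground-truth cohorts ×
200 seeds for AUC null calibration; 14-subject cohorts × 500 seeds for
the negative-$R^2$ null; 2000-subject cohorts for exchangeability; and
exhaustive enumeration up to $\binom{16}{8}$ rank assignments for the
exact Mann–Whitney oracle. These sizes were chosen so Monte-Carlo error
is comfortably below the asserted tolerances.
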