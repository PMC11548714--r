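---
title: "Methods: quality assessment of pelvic floor muscle contractions"
author: "pfmqa authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality assessment of pelvic floor muscle contractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfmqa)
```

## The problem

Pelvic floor muscle (PFM) training is the first-line conservative treatment
for urinary incontinence, but its success depends on the patient performing a
*correct* contraction. Clinically, contraction strength is graded by digital
palpation on the Modified Oxford Scale (MOS, 0 = nil … 5 = strong), which is
subjective and varies between raters. Intra-vaginal dynamometry records the
contraction objectively as a force-versus-time trace (newtons, 20 Hz native;
1024 Hz on older devices). `pfmqa` implements a complete quality-assessment
pipeline over such traces:

1. a 1D convolutional network that decides whether a trace is a PFM
   contraction at all (rest, cough and push recordings serve as
   non-contraction proxies);
2. a rule-based piecewise-linear *trapezoid model* of the 10 s maximal
   voluntary contraction (MVC), from which seven clinical features and an
   overall 0–100% rating are derived;
3. classifiers that map the normalized features to an MOS grade, scored with
   a ±1-class margin that reflects inter-rater variability of palpation.

Because clinical dynamometry datasets are private, the package ships a seeded
synthetic generator that emulates the signal statistics of the four tasks and
carries analytic ground truth; all benchmarks in the test suite run against
it.

## Down-sampling legacy recordings

Legacy 1024 Hz traces are brought to 20 Hz by low-pass filtering with a
fourth-order Butterworth at half the target rate (the new Nyquist frequency)
followed by decimation. Two implementation details are deliberate:

* **Zero-phase filtering.** The filter is applied forward and backward, so
  its magnitude response is squared and its phase is zero. A causal filter
  would lag the corner times that the feature extractor depends on.
  `signal::butter` supplies the design; the application uses odd-reflection
  padding with steady-state initial conditions so that constants pass
  unchanged and edges carry no start-up transient.
* **Non-integer decimation.** 1024/20 = 51.2, so "every Mth sample" is
  impossible with integer M; the filtered signal is instead evaluated at the
  exact target instants by linear interpolation between neighbouring
  samples.

Fidelity is quantified by reconstructing the signal on the original support
with a zero-order hold and smoothing it with the same filter, then computing
the root mean squared percentage error (RMSPE) between original and
reconstruction. The hold is *phase-centred* (each sample held over the
half-sample interval around its instant): a causal hold carries a
half-target-sample delay (25 ms at 20 Hz) which alone would dominate the
RMSPE of components of a few hertz, and centring is the same decision as
zero-phase filtering applied to reconstruction. Dominant frequencies are read
directly off the magnitude of the DFT of the mean-removed signal — no window,
no peak interpolation — which keeps the comparison between original and
down-sampled spectra exactly reproducible at bin resolution.

## The trapezoid model and its corner detectors

An MVC trace is modelled by five linear segments delimited by corners A
(trace start), B (onset), C (plateau start), D (plateau end) and E (end).
After subtracting the baseline mean (default window: the first 0.5 s) the
first derivative is taken as scaled first differences and smoothed with a
5-sample centred moving average. Detection then proceeds:

* **B and E** use a descending threshold ladder on the smoothed derivative —
  fractions (0.5, 0.25, 0.1, 0.05) of its positive extremum for the rise and
  of its negative extremum for the fall. Signed bases matter: with a common
  |max| base, a fall twice as steep as the rise shifts the first usable rise
  threshold off the mid-ramp point and onset recovery is no longer exact on
  clean data. E is found by reversing and mirroring the derivative, which
  turns the last fall into a first rise. An exceedance only counts when the
  smoothed derivative *stays* high right after it (mean of the next five
  samples above half the threshold); a lone noise spike in the baseline
  cannot pass for an onset.
* **C and D** are zero crossings of the smoothed derivative after B and
  before E, compensated for the moving-average group delay of
  `(width − 1)/2` samples, with an analogous sustained-sign confirmation so
  a noise dip in the middle of the rise is not mistaken for the plateau.
* **Refinement.** The detector corners select segment windows; least-squares
  lines through the interior of each segment (guard-trimmed by the smoothing
  half-width) are then intersected to place each corner with sub-sample
  precision. On noiseless piecewise-linear data the lines pass exactly
  through the samples, so refinement reproduces the detector corners exactly;
  under noise it is what makes ±2-sample corner accuracy reachable, since the
  derivative of a white-noise trace at 20 Hz is as loud as a typical ramp
  slope. Refinement shifts are capped at 8 samples so a contaminated window
  cannot drag a corner away from a sound detection.

Two further defaults are calibrated against the generator's task statistics
(and exposed as arguments): the threshold ladder has an absolute floor of
0.6 N/s, chosen so that rest traces (sensor noise 0.02 N) stay below it with
high probability while the weakest MVC ramps (grade 1, ≈1 N/s) remain above
it — a purely relative ladder would self-trigger on any trace — and the
moving-average width of 5 samples (250 ms) is the narrowest odd width that
suppresses single-sample noise without blurring the shortest plateaus.

## Features, normalization and the overall rating

From a fit the package computes: rising slope `m_r` (B→C), falling slope
`m_f` (D→E), area under the contraction `AUC_c` on [B, E] by the composite
trapezoidal rule (exact for on-grid piecewise-linear signals), the global
maximum `ΔF_max` on [A, E], the average force on [B, E], the contraction time
`T_c = t_E − t_B`, and muscle relaxation `ΔF_f−i` = post- minus
pre-contraction baseline mean over 0.5 s windows. The pre-contraction
baseline average `F̄_AB` is reported alongside.

Two estimator choices trade literal formulas for noise robustness while
remaining exact on clean data:

* the slopes are least-squares slopes over the segment samples
  (guard-trimmed), identical to the two-endpoint chord for collinear points
  but insensitive to single-sample noise at the corners and to ±2-sample
  corner error;
* `ΔF_max` is taken on the 5-sample-smoothed signal, because the raw maximum
  of ~170 noisy plateau samples is biased upward by the noise order statistic
  (about +5% at 2% noise — larger than the extraction-error budget on its
  own), while the smoothed maximum of a clean trapezoid is still exactly the
  plateau.

Features are min-max normalized to [0, 1] across a table of recordings; the
falling slope is scaled on its magnitude (1 = steepest descent) and the
relaxation magnitude is inverted (1 = most complete relaxation) so that every
normalized feature is oriented "higher is better". Bounds are retained and
applied to unseen rows with clipping. The overall rating is the weighted
combination

rating = (c₁·ΔF̂max + c₂·T̂c + c₃·F̂c + c₄·(m̂r + m̂f)/2 + c₅·ΔF̂f−i) × 100,

with non-negative weights summing to one (default: all 0.2), hence bounded in
[0, 100] and linear in each feature. The weights are a starting framework
meant to be refined with clinical input, not calibrated constants.

## The contraction detector

The detector is a small 1D stacked CNN: two convolution layers (32 filters,
kernel 3), each followed by batch normalization and ReLU, global average
pooling over time, and a softmax output layer — 3426 trainable parameters.
Training uses Adam (initial rate 10⁻³) on the sparse categorical
cross-entropy, batch size 32, up to 100 epochs, with the validation loss
driving both a learning-rate halving after 20 stagnant epochs and early
stopping after 50. Because no deep-learning runtime is part of the package's
dependency set, the forward and backward passes are written directly as
(shifted) matrix products on a batch-by-time flattened activation matrix,
with two small C kernels for the per-channel affine maps; the gradients are
verified against numerical differentiation in the test suite. Evaluation in
inference mode uses batch-norm population statistics re-estimated on the full
training split after training, so the model's predictions do not depend on
how many minibatch updates happened to run.

Inputs are standardized per trace (zero mean, unit variance; constant traces
become zeros) and padded or truncated symmetrically with edge values to a
fixed 200 samples (10 s at 20 Hz). Per-trace standardization is what lets a
model trained on one device transfer to another with a different force range.
Labels are binary: MVC = contraction; rest, cough and push = non-contraction.
Five-fold cross-validation stratifies folds by class at the recording level
(subject-grouped folds are available by flag), and inside each round 20% of
the training data (stratified, seeded) is held out for the early-stopping
schedule.

## The strength classifier

Normalized features map to MOS grades via one of: a random forest (RFC, 100
trees), a "top" random forest (TRFC: rank features by RFC importance, refit
on the top 4), gradient-boosted trees (XGB), or multinomial logistic
regression with a small L2 penalty (LR). Data are split 80/20 with
stratification so class imbalance is preserved. Grade 0 is excluded by
default (virtually absent in cohorts able to contract); rows annotated with
buttock movement can be dropped by flag.

Scoring uses the ±1-class margin: a prediction within one grade of the truth
is counted as the true class — it contributes a true positive to the true
class and no false positive to the neighbouring class — which reduces to the
ordinary confusion matrix at tolerance 0. Per-class precision/recall/F1 are
complemented by macro averages (macro F1 as the harmonic mean of macro P and
macro R, not the mean of per-class F1s) and count-weighted averages of the
micro form Pw = ΣTP/Σ(TP+FP), Rw = ΣTP/Σ(TP+FN); at tolerance 0 the weighted
recall equals the overall accuracy, an identity the tests assert.

## The synthetic generator

`generator_params()` defines the study conditions; the defaults are fixed
once and used by every benchmark:

| parameter | default | rationale |
|---|---|---|
| sampling rate | 20 Hz | native device rate |
| MVC / rest / push duration | 10 / 5 / 10 s | task protocol |
| MVC noise sd | 2% of plateau | sensor noise proportional to load |
| sensor noise floor | 0.02 N | ~0.1% of a 30 N full scale |
| baseline offset | 0.2–1.0 N | probe pre-load |
| grade → peak force | means 2, 6, 12, 20, 30 N, sd 20% | monotone in grade with adjacent-class overlap, so the ±1 margin is meaningful |
| rise time | 0.25–2 s; "rapid" risers draw from the short 30% of the range, half of traces | strategy variability between participants |
| fall time | 0.5–1.5 s | release faster than build-up |
| relaxation residual | 15–35% of plateau | incomplete relaxation after effort; nonzero so relative extraction errors are well defined |
| cough | 1–3 half-sine bursts, 0.3–0.5 s wide, 5–25 N | expulsive spikes, no plateau |
| push drift | 0.02–0.12 N/s | slow bearing-down drift that must stay below the onset threshold floor |

A "device B" preset (amplitudes ×0.6, noise ×1.5) emulates a second
dynamometer for the cross-device generalization benchmark. Every MVC carries
its pre-noise ground truth (corner times snapped to the sampling grid,
plateau, residual, and all feature values computed analytically), so the
extractor can be validated against it; the corner snapping is what makes the
trapezoidal-rule area *exactly* equal to the closed-form area on clean
traces.

What the generator does **not** emulate: correlated (band-limited) sensor
noise, plateau tremor and fatigue drift (a ripple option exists but defaults
to off), pre-cough counter-bracing ("knack") contractions, device saturation
and baseline wander. Passing benchmarks on this generator therefore
demonstrates the internal correctness and noise robustness of the algorithms
under white-noise conditions, not clinical performance on real recordings —
the white-noise derivative is in fact *harsher* for corner detection than a
smooth physiological trace at equal amplitude.

## Benchmark problem sizes

The test suite runs: 50 noiseless trapezoids for exact recovery; 300 noisy
MVCs for the extraction-error table (every feature's RMSPE must stay below
the predetermined 5% threshold); a 600-recording, 5-fold CV for the detector
(accuracy ≥ 0.95, sensitivity/specificity ≥ 0.90); a 450-recording device-B
evaluation for generalization (accuracy ≥ 0.90); 300 MVCs for strength
recovery (±1 accuracy ≥ 0.90 and ≥ 0.2 over the majority baseline); and 1000
random label pairs for the metric oracle. Determinism is asserted by
run-twice comparisons, with the CV pipeline re-run at a reduced size that
exercises the identical code path. `scripts/acceptance.R` recomputes the
extraction-error benchmark from scratch at the same 300-trace scale.

## Numerical choices and degenerate inputs

* RMSPE drops pairs whose reference is below 10⁻⁹ of the largest reference
  (a relative error against zero is undefined); an all-zero reference is an
  error. The error-statistics report includes the signed mean error next to
  the MAE, since a signed summary is sometimes what a comparison needs.
* The standard deviation of errors uses the n−1 denominator.
* Ties for the global maximum resolve to the first index.
* A feature constant across a normalization table is set to 0.5 with a
  warning rather than dividing by zero.
* The trapezoidal rule is the standard composite form (h/2)(f(a) + 2Σf + f(b)).
* Rest and push traces make `fit_trapezoid()` fail with a detection error
  (no sustained rise above the threshold floor) — that failure mode is part
  of the contract and is counted, not hidden, by `validate_extraction()`.
* The least-squares trapezoid fit (`fit_trapezoid_lsq()`) is provided for
  comparison: Nelder-Mead over the eight free parameters with ordering and
  slope-sign constraints as penalties and a coarse quantile-based start. On
  the noisy benchmark the rule-based extractor is at least as accurate; the
  test suite logs the comparison rather than hard-asserting it.

## Known limitations

* The CNN is trained on CPU in R; it is deliberately small, and no
  pretrained weights ship with the package.
* The ±1-margin bookkeeping for per-class metrics is one of several
  defensible conventions (a within-margin prediction is scored as the true
  class); it is stated explicitly in `evaluate_strength()` and reduces to
  the standard matrix at tolerance 0.
* Endurance, rapid-contraction and knack tasks are not scored; the feature
  set is designed to extend to them but no such scoring is implemented.
* The overall-rating weights are not clinically calibrated.
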