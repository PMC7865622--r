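---
title: "Methods: fatigue detection from wrist-IMU concentration curls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fatigue detection from wrist-IMU concentration curls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curlfatigue)
```

## The problem

A subject performs seated single-arm dumbbell concentration curls while
wearing a wrist-mounted 9-channel inertial measurement unit (IMU: 3-axis
accelerometer, gyroscope and magnetometer at 50 Hz) and a heart-rate
monitor. After every set the subject reports a Borg RPE (Rating of
Perceived Exertion, 6--20 scale). The task is to decide, per repetition,
whether the bicep is fatigued.

`curlfatigue` implements the full chain: session simulation, repetition
segmentation, RPE/heart-rate label fusion, feature extraction, correlation
screening, and classifier evaluation under two protocols.

## The exercise protocol

One session is a warm-up set of 5 repetitions followed by 5 main sets of
15 repetitions, with a 4.5 kg dumbbell. A cohort is 20 subjects, both
arms: 40 sessions and 3000 main-set repetitions. A repetition early in the
session lasts about 2 s, i.e. ~100 samples at 50 Hz.

## Labels: Borg RPE fused with heart rate

The Borg 6--20 scale is anchored so that ten times the rating approximates
heart rate in bpm. Reported ratings are subjective, so each repetition's
rating is cross-checked against the mean heart rate over the repetition:

* convergent (`|reported x 10 - HR| <= 10` bpm): keep the reported rating;
* divergent: replace it with the rounded average of the reported rating and
  `HR / 10` (round half-up, clamped to 6--20).

```{r fusion}
hrToRPE(145)                       # 14.5 Borg-equivalent
fuseRPE(17, 145, rounded = FALSE)  # (17 + 14.5) / 2 = 15.75
fuseRPE(17, 145)                   # rounds to 16
binarizeRPE(fuseRPE(17, 145))     # 16 < 17: non-fatigue
```

Fused ratings of 17--20 are *fatigue*, 6--16 *non-fatigue*. For analyses on
a continuous scale, `normalizeRPE()` min--max rescales with the maximum
fixed at 20 (the top of the scale) and the minimum set to the subject's
warm-up rating, absorbing between-subject differences in scale usage.
Rounding is *half-up* (`roundHalfUp()`), not banker's rounding: 15.75
becomes 16 and a 14.5 average becomes 15, matching how a practitioner
rounds a Borg value by hand.

## Segmentation

`detectRepetitions()` works per set on one channel (default `acc_y`, the
sideways hand vibration): a 0.3 s moving average suppresses sensor noise,
peaks at least 1 s apart and prominent above 20 % of the set's range mark
contractions, and the minima between consecutive peaks are the
trough-to-trough repetition boundaries (0-based, half-open). The first and
last repetition of a set are closed by the set boundary.

Two diagnostic tables summarize fatigue kinematics relative to the first
main set: `completionTimeTable()` (percentage increase of the mean
repetition duration per set) and `enduranceChangeTable()` (percentage
change of the mean per-repetition peak-to-trough amplitude of a gyroscope
channel --- muscular endurance shrinks as fatigue accumulates).

## Features

Eleven signals --- the nine IMU channels plus `total_acceleration`
(the placement-independent Euclidean norm of the accelerometer axes) and
`exerted_force` (`F = m a` with the dumbbell mass) --- each summarized by
three statistics per repetition window: mean, standard deviation and
average absolute deviation (AAD), giving 33 features. The standard
deviation uses divisor `N` (`sdPop()`): the window is the complete signal
of that repetition, not a sample from a larger population. AAD is
`mean(|x - mean(x)|)` and never exceeds the SD.

## Feature selection

`selectFeatures()` runs a dual Spearman screen: every feature is
rank-correlated with the fused RPE once on the fatigue-only subset and
once on the complete dataset, and a feature is kept only if its two-sided
p-value is below the allowance (`alpha = 0.1`) in *both* screens. The
lenient allowance is deliberate --- the screen is a filter before model
fitting, not a hypothesis test --- and the overlap rule protects against
features that only track exertion in the easy (non-fatigued) regime.
P-values come from `stats::cor.test`: exact (AS 89) for small tie-free
samples, asymptotic otherwise. The published significance pattern ships as
a plain-text fixture (`referenceSignificanceFlags()`); its overlap is 16
features (6 means, 5 SDs, 5 AADs).

## Models

Five families (`defaultModelSpecs()`), all on standardized features:

* **GLM** --- binomial GLM with probit link, unregularized (`stats::glm`);
* **LR** --- logistic regression with a small ridge penalty
  (`glmnet`, `lambda = 1/n`), kept distinct from GLM by link and penalty;
* **RF** --- random forest, 100 trees (`randomForest`);
* **DT** --- CART decision tree (`rpart`);
* **FNN** --- feed-forward network with two hidden layers (32 and 16 ReLU
  units), logistic output, full-batch Adam, early stopping on a 10 %
  validation split (patience 25, at most 500 epochs). It is implemented in
  plain matrix algebra inside the package because no installed R package
  offers a two-hidden-layer perceptron; at these problem sizes (hundreds
  to thousands of rows, tens of columns) full-batch training is fast and
  exactly reproducible under a seed.

## Evaluation

Two protocols, fatigue as the positive class, metrics precision / recall /
accuracy / F1 from the confusion counts:

* **Subject-specific** (`subjectSpecificEval()`): stratified 5-fold
  cross-validation within each subject, folds averaged per subject, then
  unweighted across subjects. All fold assignments are drawn *before* any
  model is trained so that seeded training cannot perturb the splits.
* **Cross-subject** (`crossSubjectLOOCV()`): leave-one-subject-out; both
  arms of a subject always stay on the same side of the split, so no
  subject leaks between train and test.

A metric with a zero denominator (e.g. precision with no positive
predictions) is reported as `NA` and excluded from averages, never imputed.
Rows are ordered canonically before folding, so results do not depend on
the input column order.

## The synthetic generator

`generateCohort()` produces the study conditions as a fully synthetic,
seeded cohort. Per repetition the motion channels carry a raised-cosine
pulse with an explicit shallow valley (5 % of the pulse amplitude) at each
boundary, so troughs are well-defined; channel amplitudes are fixed
per-channel constants modulated by subject-level and repetition-level
log-normal jitter. Key parameters of `generatorConfig()`:

* `baseRepDuration = 2.0` s --- the full trough-to-trough span, ~100
  samples at `samplingRate = 50` Hz;
* `setTimeInflation = c(0.017, 0.081, 0.143, 0.310)` --- fractional
  completion-time increase of main sets 2--5 over set 1;
* `enduranceChange = c(0.006, 0.011, -0.055, -0.041)` --- fractional
  gyroscope-amplitude change of sets 2--5 over set 1;
* `fatigueSkew = 0.8` --- fatigued repetitions get sharper, later-peaking
  pulses, giving their sample distribution a positive skew;
* `warmupRPERange = c(10, 12)`, `finalRPERange = c(17, 20)` --- the true
  RPE rises linearly across the session between integer set-end values
  (the values the subject "reports"), at most `withinSetRise = 0.9` Borg
  within a set;
* heart rate follows ten times the instantaneous true RPE plus monitor
  noise (`hrNoiseSD = 3` bpm), clipped to `hrCap = 210` bpm. Because set-end
  RPE values are integers and the within-set rise is under 1 Borg,
  reported ratings and heart rate rarely diverge (well below 10 % of
  repetitions), as in the real data.

Per-session seeds are derived from the cohort seed by a counter, so
enlarging a cohort never changes already-generated sessions.

### Realism and limits

The generator reproduces the *statistical signatures* the pipeline relies
on --- per-set timing inflation, endurance decline, fatigue skew, the
RPE/heart-rate coupling --- not bicep biomechanics. Known limits worth
stating plainly:

* Waveforms are smooth analytic pulses with Gaussian sensor noise; real
  IMU traces contain tremor harmonics, device-specific noise spectra and
  occasional artifacts.
* All features are monotone, near-linear functions of the underlying
  fatigue intensity. One consequence: the class boundary in feature space
  is close to linear, so on synthetic cohorts the probit GLM is already
  near-optimal and the neural network typically *matches* rather than
  exceeds it. The published advantage of the network on real recordings
  rests on nonlinear structure and between-subject heterogeneity that this
  generator does not model.
* Magnetometer channels are a static field plus slow drift and motion
  coupling; they carry little fatigue information by design, mirroring
  their weak role in the published screen.

## Problem sizes

All defaults are desk-scale choices of this package: a full default cohort
(40 sessions, 3200 repetitions including warm-ups) generates in well under
a minute, and the complete pipeline --- segmentation, labelling, 33
features, dual screen, five models under both protocols --- runs in a few
minutes on one CPU. Tests and examples use 2--4 subject cohorts that run
in seconds.

## Reproducibility

Every stochastic step is seeded: the generator (per-session child seeds),
fold assignment (drawn before training), and model training
(`modelSpec(seed = )`). `runPipeline()` stages all artifacts on disk as
plain text (CSV/JSON) and writes a manifest with MD5 checksums; re-running
the same configuration reproduces identical artifacts.
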