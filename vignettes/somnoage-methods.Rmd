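---
title: "Estimating physiological age from polysomnography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating physiological age from polysomnography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(somnoage)
```

## The problem

Sleep reorganizes across the lifespan in stereotyped ways: slow-wave
activity and N3 time decline, spindles become sparser, sleep fragments,
and respiratory and autonomic control degrade. A model trained to
predict chronological age from an overnight polysomnogram (PSG)
therefore learns a physiological norm, and the *age-estimate error*
(AEE = estimated minus chronological age) becomes a candidate biomarker:
a person whose sleep "looks older" than their years may carry excess
physiological burden. somnoage implements the full chain needed to study
this idea — standardized preprocessing, a two-phase sequence network,
attribution of the estimate back to signal samples, and survival
analysis linking AEE to mortality — together with a synthetic PSG
generator so that every stage can be exercised and validated without
access-restricted cohort data.

## Preprocessing

Every recording is standardized to a fixed-order `C x T` stack at
128 Hz:

1. **Resampling.** Rational-factor polyphase resampling with a
   Kaiser-window FIR anti-aliasing low-pass. The window shape (beta =
   7.86, about 80 dB of stopband rejection) and the half-length of 10
   output-rate samples per side are package defaults and are exposed as
   arguments, since only the window family is fixed by the design.
   Oxygen saturation is resampled by linear interpolation instead: it
   is a slowly varying percentage, and ringing from a sharp filter
   would manufacture artifactual desaturations.
2. **Filtering.** One elliptic family for every channel: order 16, at
   most 1 dB passband ripple, at least 40 dB stopband attenuation.
   EEG/EOG are band-passed 0.3–45 Hz, chin EMG high-passed at 10 Hz,
   ECG at 0.3 Hz, nasal pressure at 0.1 Hz, airflow and effort belts
   band-passed 0.1–15 Hz, and SaO2 is left unfiltered. Filters are
   applied forwards and backwards so the net phase is zero. Because a
   transfer-function realization of an order-16 elliptic band-pass is
   numerically hopeless, the design is carried in zero-pole-gain form
   (an analog Cauer prototype via Jacobi elliptic functions, then the
   band transform and bilinear mapping) and realized as cascaded
   second-order sections, poles nearest the unit circle last. Edge
   transients are suppressed by odd-reflection padding of three times
   the filter order. The realized response is verified in the test
   suite on dense frequency grids against the printed specifications.
3. **Normalization.** Per channel over the whole recording (windows are
   not normalized separately): an affine map sending the 5th and 95th
   amplitude percentiles to -1 and +1. SaO2 uses fixed physiological
   anchors instead — 60% maps to -1 and 100% to +1 — because its scale
   is meaningful. A constant channel normalizes to zeros and is flagged.
4. **Missing channels and inclusion.** A single missing channel is
   replaced by a flat zero row with a mask bit; more than one missing
   signal over the montage excludes the record. Recordings are also
   excluded when age is unknown, the night was a CPAP split-night, or
   total sleep time (30 s times non-wake scored epochs) is under 3 h;
   exactly 3 h is kept, since the rule excludes *less than* 3 h.

## The two-phase network

A whole night at 128 Hz is far too long to backpropagate through
directly, so the model is trained in two phases.

**Phase 1** maps a 5-minute window `x_i` (`C x 38400`) to an age
estimate: a channel-mixing 1x1 convolution, a stack of inverted
bottleneck blocks (linear expansion 1x1 convolution, depthwise temporal
convolution with stride, rectification, linear projection; residual add
when shapes match), a bidirectional LSTM over the reduced time axis,
additive attention pooling (`s_t = v' tanh(W h_t + b)`, softmax
weights), and two dense layers ending in a linear unit. The epoch latent
`z_i` concatenates the last hidden dense activation with the time
average of the Bi-LSTM output, so `M = dense_dim + 2 * lstm_hidden`
(192 at the default sizes of 64/64).

**Phase 2** stacks the latents of all `floor(T/q)` epochs into
`z in R^{M x n}` and maps the sequence through a Bi-LSTM, additive
attention and two dense layers to the final whole-night estimate. The
final estimate is the phase-2 output; phase-1 estimates act as training
scaffolding. Raw outputs may be negative; the reported estimate is
clamped at zero while the loss always sees the unclamped value.

Both phases minimize the scaled Huber objective

$$L_H(e) = \begin{cases} e^2/2 & |e| < 5 \\ 5(|e| - 5/2) & \text{otherwise} \end{cases} \bigg/ 112.5,$$

quadratic within five years and linear beyond, normalized so a 25-year
error costs exactly 1. Optimization is Adam (`beta1 = 0.9`,
`beta2 = 0.999`) with L2 weight decay on weight matrices only, never on
biases, early stopping on validation loss, and the best-validation
checkpoint returned.

### Numerical and design choices

Several choices were genuinely open and are worth recording:

* **Depthwise kernels default to kernel = stride.** The windows then
  tile the time axis and the convolution collapses to a single dense
  matrix product, which is what makes CPU-only training practical. The
  kernel length remains configurable for overlapping windows.
* **Rectification sits after the depthwise stage**, not before it.
  The 1x1 stages are purely cross-channel, so the depthwise convolution
  is the only temporal filter in a block; applying it to the raw
  (linear) signal lets kernels act as band-pass filters whose rectified
  outputs are band envelopes — the features that age prediction from
  EEG actually needs. With the opposite order the stem can only see
  broadband envelopes, which per-night percentile normalization has
  already flattened, and desk-scale optimization stalls at the
  predict-the-mean solution.
* **Rectifiers are leaky** (slope 0.01 on the negative side). With few
  gradient steps and narrow layers, a hard rectifier can silence a head
  unit for half of its input space permanently; the observed failure
  mode is a night-level head that collapses younger subjects onto a
  single constant prediction. The leak keeps a gradient path open at
  negligible cost to expressiveness.
* **Initialization.** He-uniform weights (bound `sqrt(6/fan_in)`);
  depthwise kernels start as a coarse cosine filter bank with
  frequencies spread over channels; the pre-ReLU dense bias starts at
  0.1 so no head unit is born dead; the output layer is a fixed scale
  of 25 years per unit activation with its bias initialized at the
  training-label mean. Each choice removes a distinct slow-start
  failure mode observed at small scale: vanishing activation variance,
  no frequency selectivity at initialization, dead rectifiers, and an
  output that must traverse decades of years with O(1) weights.
* **Phase-1 labels.** Every 5-minute epoch of a night carries the
  subject's age; no per-epoch age exists.
* **Splitting.** The uniform-age split greedily removes one member of
  the most represented (integer age, then cohort, then sex) cell until
  the target training size remains, repeats on the removals for
  validation, and forces CPAP users and subjects with neurological
  disorders into the test set. Ties are broken by seeded uniform
  choice, and the split is by subject so repeat nights never straddle
  sets.

## Interpretation

Relevance is attributed with expected gradients against the all-zero
baseline: draw `alpha ~ U(0,1)` (optionally with small input noise,
default sd 0.09, 64 draws), average the input gradient at the
interpolated points, and multiply elementwise by the input. For a
linear model this equals `w * x` exactly, and in general the scores sum
approximately to the output change from baseline; both properties are
pinned in the tests. Scores are smoothed per channel with a unit-sum
Gaussian window (10 s length, 0.234 s standard deviation — 1280 samples
and sigma = 29.952 samples at 128 Hz), averaged across channels, and
averaged time-locked to event onsets or stage-transition anchors (the
start of the first epoch of the new stage, keyed by the from/to pair).
Smoothing and channel averaging are both linear, so their order is
immaterial; the package smooths first. Anchors without a full window of
context are dropped and counted; the mean is reported with the standard
error across anchors.

## Survival analysis

AEE regresses toward the mean, so it carries a spurious negative age
trend; the age-corrected error AEEc is defined as the residual of the
OLS regression of AEE on an intercept and age, exactly orthogonal to
age by the normal equations. Cox proportional-hazards models (Efron tie
handling, via the survival package) relate mortality to AEE under three
covariate sets: model 1 adjusts for age; model 2 adds sex, BMI, race,
smoking, education, alcohol, caffeine, benzodiazepines, sedatives,
antidepressants and cohort; model 3 adds WASO, N2%, REM%, arousal and
apnea-hypopnea indices, time below 80% saturation, sleepiness score and
comorbidities (hypertension, CHF, heart attack, stroke, type-2
diabetes, COPD — the last included by default with a flag to drop it,
as the specifications differ on it). Hazard ratios are reported per
10-year AEE increment, `HR = exp(10 beta)`, with Wald 95% intervals.
The proportional-hazards assumption is checked through scaled
Schoenfeld residuals against time.

The baseline survival (the curve of a reference subject with every
covariate at its median — mean available by flag) is extended with a
Weibull law `S(t) = exp(-(t/lambda)^k)` fitted by least squares on
`log(-log S)` against `log t` over the usable steps (those strictly
inside (0,1)). Life expectancy at an index age of 40, 60 or 80 is the
integral of `S(t)^z` over all time (adaptive quadrature, relative
tolerance 1e-6), with the other covariates at their policy value within
ten years of the index age, and the headline contrast is the difference
in life expectancy between AEE = -10 and AEE = +10 years. Missing
covariates are imputed by a simple declared policy — per-cohort median
or mode — rather than chained equations, and CPAP users are excluded
from the survival sample. Cardiovascular mortality is handled
cause-specifically, censoring other deaths.

## The synthetic cohort

The generator emulates the aging signatures the pipeline is meant to
detect, with a per-subject "excess aging" offset delta (zero-mean,
sd 7.5 years) entering everywhere chronological age does:

* a semi-Markov hypnogram whose N3 dwell and entry probability decline
  and whose wake intrusions increase with effective age;
* EEG as stage-gated band-limited noise — delta-band amplitude
  `70 - 0.625 (age + delta)` microvolts against a fixed ~10 microvolt
  broadband background — plus 12 Hz spindle bursts in N2 (rate
  `3.5 - 0.03 age_eff` per minute) and high-beta arousal bursts at
  `1 + 0.25 age_eff` per hour;
* apneas at `max(0, 2 + 0.35 (age_eff - 20))` per hour gating airflow
  and nasal pressure to near zero with lagged SaO2 desaturations;
* an ECG beat train with heart rate rising and RR variability falling
  in effective age; EOG and chin EMG with stage-appropriate amplitudes.

Survival times follow a proportional-hazards Weibull law
`S(t|subject) = exp(-(t/40)^{1.4} exp(0.09 (age - 60) + beta_delta
delta))` with administrative censoring at 15 years and `beta_delta =
0.0255` per year by default — the log-hazard that corresponds to a
hazard ratio of about 1.29 per 10 years, the order of magnitude a
sleep-age biomarker plausibly carries. Everything is driven by one
cohort seed with per-subject seeds derived by hashing, so any subject
can be regenerated in isolation; `cohort_truth()` exposes the draw so
large cohorts can be generated, preprocessed and discarded one subject
at a time.

What the generator does *not* emulate matters for interpreting green
tests: real EEG microstructure (K-complexes, topography, artifacts),
inter-cohort montage and scoring heterogeneity, and real covariate
correlation structures are all absent. Passing the recovery tests shows
the pipeline is implemented correctly and can extract a planted
age signal end to end; it does not certify performance on clinical
recordings.

## Problem sizes used in the packaged checks

The packaged end-to-end check trains a deliberately small two-phase
model (mixer width 4, three blocks of widths 8/16/16 with strides
16/4/4, Bi-LSTM hidden size 8, latent M = 21) on a 150-subject cohort
of 2-hour recordings with central EEG only, split 105/23/22 by the
uniform-age algorithm. Success is defined relative to the data: test
MAE below 0.7 of the mean-predictor MAE and a positive Spearman
correlation (> 0.3) between AEE and the planted delta. The Cox and
life-expectancy chains are checked on tabular cohorts of 1500–2000
subjects with 200 seeded replicates, against brute-force
partial-likelihood maximization on hand-built datasets, closed-form
exponential life expectancy, and exact Weibull recovery. These sizes
are the package's chosen desk-scale study conditions; the same code
paths scale to full cohorts by changing the configuration objects.

## Known limitations

* The network architecture follows the published structural recipe but
  its exact hyperparameters are not public; the defaults here are the
  package's own and are configuration-exposed.
* Training is plain R linear algebra: practical for the desk-scale
  study conditions and for method development, not for thousands of
  full nights.
* The Weibull tail fit is a least-squares convenience; an
  interval-censored maximum-likelihood alternative would weigh late
  steps differently when events are sparse.
* Attention weights are not offered as interpretation; attribution
  goes through expected gradients only.
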