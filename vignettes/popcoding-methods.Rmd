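---
title: "Methods: models, parameters and design choices in popcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in popcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`popcoding` is a pipeline for asking how a genetic or pharmacological
manipulation changes the way a visual-cortex population encodes stimuli, at
three levels: single-neuron response properties, single-neuron encoding
models, and population decoding. Because such studies rarely ship raw
imaging data, the package pairs every analysis stage with a synthetic
session generator whose ground truth is known, so the whole chain can be
validated quantitatively. This vignette documents the models, the tunable
parameters, the numerical choices and the known limitations.

## The synthetic session generator

A session is simulated in five seeded stages (one master seed, per-stage
sub-seeds derived deterministically):

1. **Protocol.** Three session types mirror a standard awake-imaging
   battery: 640 s of gray screen; 16 trials of 8 drifting-grating directions
   (2 s ON after a 3 s OFF period; 128 presentations, 640 s); and 32 trials
   of 7 consecutive 2 s natural-movie clips after a 3 s OFF period
   (224 presentations, 544 s). Frame rate defaults to 16 Hz.
2. **Ground truth.** Neurons are partitioned into stimulus-tuned (70%),
   behavior-coupled (20%), pure-noise (10%) and untuned classes. Tuned
   neurons get a preferred direction uniform over the 8 protocol directions
   and a log-normal peak evoked rate around `evoked_rate_hz` (4 Hz).
   Direction tuning is von Mises, `exp(kappa*(cos(delta)-1))` with
   `tuning_kappa = 2`: the standard circular tuning family, with a single
   bandwidth knob that maps monotonically onto OSI.
3. **Rates.** `rate = baseline + jitter * gain * tuning * envelope +
   behavior + latent`, clipped at 0. The per-presentation jitter is
   log-normal with mean 1 and log-SD `trial_noise_sd`. Behavioral drive is
   linear in z-scored running speed and pupil diameter (both log-domain
   Ornstein–Uhlenbeck processes, time constants 3 s and 5 s, so they are
   slow, positive and mean-reverting). Shared variability is a rank-
   `latent_dim` AR(1) factor model. For movie sessions each clip carries a
   fixed smooth positive temporal envelope (log-Gaussian, depth 2) shared
   across trials, giving repeated trials a common time course — without it,
   per-frame Poisson noise dominates and trial-to-trial reliability is not a
   meaningful quantity.
4. **Spikes.** Inhomogeneous Poisson counts per frame at `rate/frame_rate`.
   Spiking at frame resolution suffices because every downstream analysis is
   frame-based.
5. **Fluorescence.** Each spike adds `spike_amplitude` (10 a.u.) to a
   calcium trace decaying with `calcium_tau_s = 0.5` s (a red-indicator-like
   constant); traces sit on a 100 a.u. baseline, receive Gaussian noise
   (SD 2) and a per-neuron share of a common slow neuropil signal. The
   per-neuron neuropil coupling is jittered (+/-20% around 0.7) and the
   emitted neuropil channel carries its own measurement noise, so the fixed
   0.7-coefficient correction downstream is a deliberately *imperfect*
   inversion, as with real recordings.

### Condition presets and their calibration

The manipulated condition ("knockout") differs from control along exactly
three axes, matching the three single-neuron phenotypes such manipulations
produce — lower firing, smaller maximal responses, lower reliability —
while leaving the correlation structure (latent dimensionality and
loadings) untouched:

| knob | control | knockout |
|---|---|---|
| `gain_factor` (evoked gain) | 1.0 | 0.5 |
| `baseline_rate_hz` | 0.2 | 0.12 |
| `trial_noise_sd` | 0.3 | 0.8 |

No quantitative effect sizes are published for this phenotype, so these are
calibration choices, made once against the qualitative figure-level
effects: a ~40–50% reduction in mean maximal response, a clearly reduced
median reliability, and a population-decoding deficit of roughly 0.1 AUROC
at 25 neurons, with the OSI distribution essentially unchanged.

Two calibration notes are worth recording. First, the spontaneous rate is
0.2 Hz (physiological for superficial-layer excitatory neurons) rather than
higher values, because baseline activity contributes an additive dF/F
offset to measured responses that does not scale with evoked gain; at
0.5 Hz this offset biases measured OSI downward in a gain-dependent way and
breaks the intended dissociation between "smaller responses" and
"unchanged selectivity". Second, an evoked-gain change alone moves the
measured mean maximal response almost proportionally (a 0.6 gain yields a
measured ratio of ~0.6), which is what makes gain a clean, recoverable
knob.

## Preprocessing

* **Neuropil correction** is the fixed-coefficient subtraction
  `F_roi = F_raw - 0.7 * F_neuropil`.
* **Baseline F0** is the mode of a Gaussian kernel density estimate of the
  corrected trace (Silverman rule-of-thumb bandwidth, 512-point grid
  spanning the data range). The mode is robust to the sparse, skewed
  transients riding on the baseline. Neurons with nonpositive F0 cannot be
  normalized; they are excluded (rows set `NA`) and reported, never
  clamped.
* **dF/F** is `(F_roi - F0) / F0`; the pipeline is exactly invariant to a
  common rescaling of raw and neuropil fluorescence.
* **Deconvolution** estimates nonnegative event amplitudes `e` minimizing
  `||dff - K e||^2` with `K` the causal exponential kernel
  (`exp(-1/(tau*fs))` per-frame decay, `tau = 0.5` s by default). The
  problem is solved *exactly* in linear time per trace by
  pool-adjacent-violators on the equivalent isotonic reformulation
  (`c_t >= gamma * c_(t-1)`); tests verify the minimizer against a dense
  active-set NNLS oracle. This is a deterministic, verifiable stand-in for
  pipeline-specific spike inference, sufficient for the rank and rate
  statistics used downstream.
* **Firing rate** counts suprathreshold event frames per second. The
  default threshold is 0 (every strictly positive event frame counts); on
  noisy recordings the examples use a small amplitude threshold (half the
  single-event dF/F amplitude, 0.05) because least-squares deconvolution
  fits part of the noise with micro-events.

## Response metrics

Responses are trial means over a window from stimulus onset (2 s for
gratings; for movies the clip duration for metrics and a configurable 3 s
for decoding — note the 3 s window necessarily overlaps the next clip, a
property of the stated design that users should keep in mind).

* **Visual responsiveness**: one-way ANOVA of single-trial responses across
  the 8 conditions plus the blank (pre-stimulus OFF window) at p < 0.01,
  *and* best-condition mean above blank mean. The criterion is
  null-calibrated: on pure-noise neurons the flag rate stays below 1.5%.
* **Tuning**: per-direction trial means (+/- SEM); preferred direction by
  argmax with ties to the lowest index (the convention used for every
  tie-break in the package); maximum response is the mean at the preferred
  direction; curves are re-centered on the preferred direction for
  population averages.
* **OSI**: responses floored at 0, opposite directions averaged into 4
  orientations, `(R_pref - R_orth) / (R_pref + R_orth)` with `R_orth` 90
  degrees away, clipped to [0, 1]; degenerate curves return 0 and are
  flagged. OSI is exactly invariant to multiplicative scaling of the curve.
* **Reliability**: mean Pearson correlation over all trial pairs of the
  within-window time courses for one stimulus; the neuron-level value is
  taken at the neuron's preferred stimulus (highest trial-mean response).
  Pairs with a zero-variance trial are skipped and counted, never
  zero-filled.
* **Correlations**: pairwise (concatenated activity vectors), signal
  (trial-averaged condition vectors) and noise (per-condition z-scored
  trials, concatenated). Constant vectors are excluded with a report;
  conditions with zero trial variance are dropped pairwise.

## Encoding models

The single-neuron encoding model is a linear-link lasso GLM of the dF/F
trace on 8 x 32 binary stimulus indicators (one per direction and frame lag
over a [0, 2] s window at 16 Hz) plus z-scored pupil and running
covariates, with `lambda = 1e-3` and 10-fold cross-validation. Design and
numerical choices:

* **Contiguous temporal folds.** Calcium traces are strongly
  autocorrelated; frame-shuffled folds leak training signal into the test
  block and inflate held-out R². All fold R² values use
  `1 - SS_res/SS_tot` with the test block's own mean, so a null model
  scores at or below zero.
* **Solver-internal predictor standardization.** The solver standardizes
  predictors internally and reports weights on the original scale — the
  default behavior of the reference implementations this pipeline mirrors.
  It matters: a sparse 0/1 indicator column (16 ones among 10240 frames)
  has a tiny raw scale, and without standardization the penalty removes
  every stimulus column at this lambda.
* **Partial models by refitting.** Group significance compares fold-wise
  full-model R² against a *refit* with the group's columns zeroed (not a
  prediction with weights zeroed), via a paired two-sided t-test across the
  10 folds, Holm-corrected over the three groups (stimulus, pupil,
  running), requiring the full model to win on average. Under pure-noise
  targets the family-wise error stays below 7% at alpha = 0.05; at the
  generator's default SNR the power for stimulus-tuned neurons exceeds
  90%.
* **Continuous covariates** are re-z-scored with training-block statistics
  only; test blocks reuse them (no leakage).

The population-activity model predicts one neuron's trace from k randomly
sampled other neurons (10 random predictor sets by default, averaged). The
target trace is standardized once (held-out R² is scale-invariant) and
predictors are z-scored per training block, so lasso weights are on an
SD-per-SD scale and the 0.05 / 0.1 weight-magnitude bins are comparable
across neurons. One caveat from the generator's own noise floor: the
maximum over k = 20 weights on ~10000-frame autocorrelated traces is ~0.15
even for unpredictable targets, so the "above 0.1" bin fraction does not by
itself separate conditions here; the mean held-out R² (and, directionally,
the median maximum weight) does.

## Decoding

Stimulus identity is decoded from trial features (per-neuron mean dF/F over
the stimulus window) with linear one-vs-rest maximum-margin classifiers:

* **Balanced splits.** Class counts are equalized (downsampling to the
  minimum by a seeded permutation, first-k rule), then `ceiling(0.33 * n)`
  trials per class are held out; both sides are class-balanced, so chance
  is well-defined.
* **Grid search.** The regularization value is chosen from
  `10^-3 ... 10^3` by inner 3-fold cross-validated multiclass accuracy
  (argmax over one-vs-rest decision scores); ties break to the smallest
  value. A linear kernel with a single regularization parameter is the
  family consistent with a one-dimensional grid.
* **Macro AUROC.** Per class, the binary AUROC of the class's continuous
  decision scores against the rest (ties count half — the Mann–Whitney
  identity, verified against an exhaustive pairwise oracle); macro-averaged
  over the 8 (or 7) classes. AUROC is invariant to any strictly monotone
  transform of the scores.
* **Feature scaling** uses training-split statistics only.
* **Sweeps and nulls.** Population sizes 5–25 in steps of 5, 50 random
  subsets per size by default, each with a paired label-shuffled control
  (same subset, same split seed). Group comparisons use a two-way ANOVA
  (group x population size).

## Group statistics

Neuron-level metrics are nested within animals; treating neurons as
independent replicates is pseudoreplication. `lme_group_compare()` fits
`value ~ group + (1 | animal)` (random intercept per animal; session-level
nesting available via an argument) and reports the two-tailed t-statistic
with Satterthwaite degrees of freedom, as provided by the fitting library
and recorded in the output. In simulations with animal-level shifts and no
group effect the mixed model keeps its false-positive rate near nominal
while the naive neuron-level t-test exceeds 30%. Groups with a single
animal fall back to a fixed-effects model with a warning. Mann–Whitney,
Kolmogorov–Smirnov and t tests are thin wrappers returning standardized
comparison rows.

## Problem sizes and runtime choices

The test suite and the acceptance script run complete analyses at sizes
chosen to keep a full run on one CPU comfortable while leaving all
statistical conclusions stable: sessions of 30–100 neurons at 16 Hz for
metrics, decoding sweeps with 10–15 subsets per population size, and the
large significance-calibration simulations (1000 null neurons) on a 4 Hz
variant of the grating session, where the design matrix is 2560 frames by
66 columns — the calibration properties (family-wise error, power at
default SNR) are invariant to this choice of temporal resolution.

## Limitations

The generator emulates the statistical structure the analyses consume —
tuning, trial variability, behavioral coupling, shared latents, calcium
dynamics, neuropil contamination — not imaging physics: no motion
artifacts, ROI overlap, slow drift, bleaching, or segmentation errors, and
spiking is Poisson at frame resolution with linear behavioral coupling.
Passing tests therefore validate the *analysis chain* under a faithful
statistical model of the data, not robustness to acquisition artifacts.
Deconvolution assumes a single known exponential; indicator nonlinearity
and saturation are not modeled. Real effect sizes of any particular
manipulation are unknown; the condition presets are calibrated stand-ins,
and conclusions about a real dataset require the real recordings.
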