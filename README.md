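# popcoding

Population coding analysis for two-photon calcium imaging in visual
cortex — a tested R pipeline for quantifying how an experimental
manipulation (e.g. an astrocytic gene knockout) changes single-neuron
response properties, stimulus/behavior encoding, and population-level
stimulus decoding. It is aimed at systems neuroscientists who have
fluorescence trace matrices plus a stimulus protocol and want the full
chain — preprocessing, response metrics, encoding GLMs, SVM decoding,
mixed-effects group statistics — in one auditable, seedable toolbox, and
at methodologists who want every stage verifiable against synthetic data
with known ground truth.

## What it computes

**Preprocessing.** Neuropil correction `F_roi = F_raw − 0.7·F_neuropil`;
baseline `F0` as the mode of a Gaussian kernel density of the trace;
`ΔF/F = (F − F0)/F0`; nonnegative deconvolution of ΔF/F against a causal
exponential kernel (decay `exp(−1/(τ·fs))`), solved exactly by
pool-adjacent-violators on the isotonic reformulation; firing rates as
suprathreshold event frames per second.

**Response metrics.** Trial tensors (neuron × condition × trial) over
stimulus windows; visual responsiveness (ANOVA across conditions + blank,
p < 0.01, peak > blank); orientation tuning with
`OSI = (R_pref − R_orth)/(R_pref + R_orth)` on orientation-collapsed
curves; maximum response at the preferred direction; trial-to-trial
reliability (mean Pearson correlation over all trial pairs of movie
response time courses); pairwise, signal and noise correlations.

**Encoding models.** Per neuron, a linear-link lasso GLM
`r_n(t) = Σ_c Σ_{t_s} β_c^{t_s} x_c(t−t_s) + Σ_b β_b x_b(t) + ε`
with 8 directions × 32 frame lags over a [0, 2] s window plus z-scored
pupil and running covariates, λ = 10⁻³, contiguous 10-fold CV, held-out
R²; predictor-group significance by refitting with the group's columns
zeroed and a paired t-test across folds with Holm correction. A
population-activity variant predicts each neuron from k sampled neighbors
and bins the maximum weight at 0.05/0.1.

**Decoding.** Class-balanced 33% holdout, linear one-vs-rest SVMs with a
10⁻³…10³ regularization grid search, macro-averaged one-vs-rest AUROC from
decision scores, paired label-shuffle nulls, population-size sweeps
(5–25 neurons), two-way ANOVA between groups.

**Group statistics.** `value ~ group + (1 | animal)` mixed models
(two-tailed t, Satterthwaite df) guarding against pseudoreplication of
neuron-level observations, plus Mann–Whitney, KS and t-test wrappers.

**Synthetic sessions.** A seeded generator producing gray-screen,
drifting-grating (16 trials × 8 directions, 2 s ON / 3 s OFF) and
natural-movie (32 trials × 7 clips) sessions: von Mises tuning, log-normal
per-trial gain jitter, Poisson spiking, exponential calcium kernels,
shared neuropil, behavioral coupling and latent covariability — with
control/knockout presets differing in evoked gain, baseline rate and trial
noise only.

## Worked example

```r
library(popcoding)

cfg <- sim_config(n_neurons = 40, condition = "control", seed = 42)
session <- simulate_session("gratings", cfg)
session
#> <synthetic_session> control, gratings
#> <pop_recording> 40 neurons x 10240 frames @ 16 Hz (+behavior)

dff <- compute_dff(session$recording)
tensor <- build_trial_tensor(dff, session$protocol, window_s = 2)
compute_tuning(tensor)
#> <tuning_result> 40 neurons; median OSI 0.541, median max response 0.1111

responsive <- classify_visually_responsive(
  tensor, blank_responses(dff, session$protocol, 2))
sum(responsive)
#> [1] 28

features <- build_feature_matrix(dff, session$protocol, window_s = 2)
decode_once(features$X[, 1:25], features$labels,
            decoding_config(), seed = 1)$auroc
#> [1] 0.9474206
```

A 40-neuron control session yields a median OSI of 0.54 over all neurons,
28/40 neurons passing the responsiveness criterion (the generator made 70%
tuned), and a 25-neuron decoder reading out the 8 grating directions at
AUROC ≈ 0.95 against a label-shuffle null of ≈ 0.48 — i.e. far above
chance (0.5).

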