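#' Simulation configuration for a synthetic population
#'
#' Bundles every knob of the synthetic-session generator. The `condition`
#' presets encode the three axes along which the knockout phenotype is
#' emulated: a multiplicative evoked-gain reduction (`gain_factor`), a lower
#' spontaneous rate (`baseline_rate_hz`) and a larger trial-to-trial
#' multiplicative gain jitter (`trial_noise_sd`). Correlation structure
#' (latent dimensionality and loadings) is deliberately shared between
#' conditions.
#'
#' @param n_neurons number of neurons to simulate.
#' @param condition `"control"` or `"knockout"`; selects preset values for
#'   `gain_factor`, `baseline_rate_hz` and `trial_noise_sd` unless those are
#'   given explicitly.
#' @param frame_rate_hz imaging frame rate in Hz.
#' @param gain_factor multiplicative gain on the evoked (stimulus-driven)
#'   rate; the knockout preset uses 0.5.
#' @param baseline_rate_hz spontaneous firing rate in Hz.
#' @param evoked_rate_hz mean peak evoked rate (Hz) of tuned neurons at their
#'   preferred direction, before `gain_factor`.
#' @param trial_noise_sd standard deviation (log scale) of the log-normal
#'   per-trial multiplicative gain jitter; the jitter has mean 1.
#' @param tuning_kappa von Mises concentration of the direction tuning curve.
#' @param frac_tuned,frac_behavior_coupled,frac_noise disjoint fractions of
#'   neurons that are stimulus-tuned, behavior-coupled, or pure-noise
#'   (baseline only, no shared variability); must sum to at most 1, the
#'   remainder being untuned neurons that still carry the shared latent.
#' @param latent_dim number of shared latent variability dimensions.
#' @param latent_sd_hz standard deviation (Hz) of latent loadings.
#' @param behavior_weight_hz typical rate modulation (Hz per z-unit) of
#'   behavior-coupled neurons.
#' @param calcium_tau_s calcium indicator decay time constant in seconds.
#' @param spike_amplitude fluorescence units added per deconvolved event.
#' @param baseline_fluo constant fluorescence offset of each cell.
#' @param noise_sd_fluo additive Gaussian fluorescence noise SD.
#' @param neuropil_coupling fraction of the shared neuropil signal mixed into
#'   each raw trace (jittered per neuron so the fixed-coefficient correction
#'   is an imperfect inversion, as in real data).
#' @param seed master seed; per-stage sub-seeds are derived deterministically.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_neurons = 20, condition = "knockout", seed = 1)
#' cfg$gain_factor
#' @export
sim_config <- function(n_neurons,
                       condition = c("control", "knockout"),
                       frame_rate_hz = 16,
                       gain_factor = NULL,
                       baseline_rate_hz = NULL,
                       evoked_rate_hz = 4,
                       trial_noise_sd = NULL,
                       tuning_kappa = 2,
                       frac_tuned = 0.7,
                       frac_behavior_coupled = 0.2,
                       frac_noise = 0.1,
                       latent_dim = 1,
                       latent_sd_hz = 0.3,
                       behavior_weight_hz = 0.5,
                       calcium_tau_s = 0.5,
                       spike_amplitude = 10,
                       baseline_fluo = 100,
                       noise_sd_fluo = 2,
                       neuropil_coupling = 0.7,
                       seed = 1L) {
  condition <- match.arg(condition)
  preset <- switch(condition,
    control  = list(gain_factor = 1.0, baseline_rate_hz = 0.2, trial_noise_sd = 0.3),
    knockout = list(gain_factor = 0.5, baseline_rate_hz = 0.12, trial_noise_sd = 0.8)
  )
  cfg <- list(
    n_neurons = as.integer(n_neurons),
    condition = condition,
    frame_rate_hz = frame_rate_hz,
    gain_factor = gain_factor %||% preset$gain_factor,
    baseline_rate_hz = baseline_rate_hz %||% preset$baseline_rate_hz,
    evoked_rate_hz = evoked_rate_hz,
    trial_noise_sd = trial_noise_sd %||% preset$trial_noise_sd,
    tuning_kappa = tuning_kappa,
    frac_tuned = frac_tuned,
    frac_behavior_coupled = frac_behavior_coupled,
    frac_noise = frac_noise,
    latent_dim = as.integer(latent_dim),
    latent_sd_hz = latent_sd_hz,
    behavior_weight_hz = behavior_weight_hz,
    calcium_tau_s = calcium_tau_s,
    spike_amplitude = spike_amplitude,
    baseline_fluo = baseline_fluo,
    noise_sd_fluo = noise_sd_fluo,
    neuropil_coupling = neuropil_coupling,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_neurons >= 1L)
  if (!is.finite(cfg$frame_rate_hz) || cfg$frame_rate_hz <= 0) {
    stop("frame_rate_hz must be > 0")
  }
  nonneg <- c("gain_factor", "baseline_rate_hz", "evoked_rate_hz",
              "trial_noise_sd", "tuning_kappa", "latent_sd_hz",
              "calcium_tau_s", "spike_amplitude", "noise_sd_fluo")
  for (f in nonneg) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0) stop(f, " must be >= 0")
  }
  fr <- c(cfg$frac_tuned, cfg$frac_behavior_coupled, cfg$frac_noise)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1 + 1e-12) {
    stop("neuron-class fractions must lie in [0,1] and sum to at most 1")
  }
  if (cfg$latent_dim < 0L) stop("latent_dim must be >= 0")
  if (cfg$neuropil_coupling < 0 || cfg$neuropil_coupling > 1) {
    stop("neuropil_coupling must lie in [0,1]")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d neurons, %s, %g Hz\n  gain %.2f | baseline %.2f Hz | trial-noise sd %.2f | kappa %.1f\n",
    x$n_neurons, x$condition, x$frame_rate_hz,
    x$gain_factor, x$baseline_rate_hz, x$trial_noise_sd, x$tuning_kappa))
  invisible(x)
}
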