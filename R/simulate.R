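#' Draw the ground-truth parameters of a synthetic population
#'
#' Neurons are partitioned into four disjoint classes by the config
#' fractions: stimulus-tuned, behavior-coupled, pure-noise (baseline firing
#' only, no shared variability) and plain untuned (baseline plus shared
#' latent). Tuned neurons get a preferred direction drawn uniformly from the
#' 8 protocol directions and a log-normal peak evoked rate around
#' `evoked_rate_hz`; behavior-coupled neurons get running/pupil weights.
#'
#' @param config a [sim_config()].
#' @return A `ground_truth` list: `preferred_direction` (degrees in
#'   \[0,360)), `tuning_gain` (Hz, 0 for untuned), `behavior_weights`
#'   (n x 2 matrix, columns running/pupil, Hz per z-unit), `is_tuned`,
#'   `is_behavior_coupled`, `latent_loadings` (n x latent_dim, Hz).
#' @export
make_population <- function(config) {
  validate_sim_config(config)
  n <- config$n_neurons
  with_seed(derive_seed(config$seed, 1L), {
    n_tuned <- round(config$frac_tuned * n)
    n_beh   <- round(config$frac_behavior_coupled * n)
    n_noise <- round(config$frac_noise * n)
    if (n_tuned + n_beh + n_noise > n) n_noise <- n - n_tuned - n_beh
    cls <- rep.int("untuned", n)
    ord <- sample.int(n)
    cls[ord[seq_len(n_tuned)]] <- "tuned"
    if (n_beh > 0) cls[ord[n_tuned + seq_len(n_beh)]] <- "behavior"
    if (n_noise > 0) cls[ord[n_tuned + n_beh + seq_len(n_noise)]] <- "noise"

    is_tuned <- cls == "tuned"
    is_beh <- cls == "behavior"
    pref <- sample(seq(0, 315, by = 45), n, replace = TRUE)
    pref[!is_tuned] <- 0
    gain <- rlnorm(n, meanlog = log(config$evoked_rate_hz) - 0.125, sdlog = 0.5)
    gain[!is_tuned] <- 0
    bw <- matrix(0, n, 2, dimnames = list(NULL, c("running", "pupil")))
    if (any(is_beh)) {
      bw[is_beh, ] <- rnorm(2 * sum(is_beh), mean = config$behavior_weight_hz,
                            sd = config$behavior_weight_hz / 3)
    }
    load <- matrix(0, n, config$latent_dim)
    if (config$latent_dim > 0) {
      keep <- cls != "noise"
      load[keep, ] <- rnorm(sum(keep) * config$latent_dim,
                            sd = config$latent_sd_hz)
    }
    structure(list(preferred_direction = pref,
                   tuning_gain = gain,
                   behavior_weights = bw,
                   is_tuned = is_tuned,
                   is_behavior_coupled = is_beh,
                   latent_loadings = load),
              class = "ground_truth")
  })
}

# Discrete log-domain Ornstein-Uhlenbeck process: positive, mean-reverting,
# lag-1 autocorrelation 1 - dt/tau.
log_ou <- function(n_frames, dt, mean_value, sd_log, tau_s) {
  mu <- log(mean_value)
  x <- rep(mu, n_frames)
  if (sd_log > 0 && n_frames > 1) {
    a <- dt / tau_s
    eps <- rnorm(n_frames - 1L, sd = sd_log * sqrt(2 * a))
    for (t in 2:n_frames) x[t] <- x[t - 1] + a * (mu - x[t - 1]) + eps[t - 1]
  }
  exp(x)
}

#' Simulate behavioral covariates (running speed and pupil diameter)
#'
#' Two independent, slowly varying, strictly positive mean-reverting series
#' (log-domain Ornstein-Uhlenbeck), emulating locomotion and pupil dynamics
#' recorded alongside imaging.
#'
#' @param n_frames number of frames.
#' @param frame_rate_hz frame rate in Hz.
#' @param seed integer seed.
#' @param running_mean,pupil_mean stationary means (cm/s and mm).
#' @param running_sd_log,pupil_sd_log stationary SD on the log scale; 0 gives
#'   a constant series at the mean.
#' @param running_tau_s,pupil_tau_s mean-reversion time constants (s).
#' @return data.frame with columns `running` and `pupil`, `n_frames` rows.
#' @export
simulate_behavior <- function(n_frames, frame_rate_hz = 16, seed = 1L,
                              running_mean = 5, running_sd_log = 0.5,
                              running_tau_s = 3,
                              pupil_mean = 2, pupil_sd_log = 0.2,
                              pupil_tau_s = 5) {
  stopifnot(n_frames > 0, frame_rate_hz > 0)
  dt <- 1 / frame_rate_hz
  with_seed(seed, {
    data.frame(
      running = log_ou(n_frames, dt, running_mean, running_sd_log, running_tau_s),
      pupil   = log_ou(n_frames, dt, pupil_mean, pupil_sd_log, pupil_tau_s))
  })
}

# Von Mises direction tuning, peak-normalized to 1 at delta = 0.
von_mises_tuning <- function(delta_deg, kappa) {
  exp(kappa * (cos(delta_deg * pi / 180) - 1))
}

# Smooth positive within-clip temporal envelopes (mean ~1), fixed per
# condition across trials and neurons; gives movie responses a repeatable
# time course so trial-to-trial reliability is well defined.
clip_envelopes <- function(n_conditions, duration_frames, seed) {
  with_seed(seed, {
    env <- matrix(0, n_conditions, duration_frames)
    for (c in seq_len(n_conditions)) {
      w <- rnorm(duration_frames)
      k <- dnorm(seq(-2, 2, length.out = 7))
      sm <- stats::filter(c(rep(w[1], 3), w, rep(w[duration_frames], 3)),
                          k / sum(k), sides = 2)
      sm <- as.numeric(sm)[3 + seq_len(duration_frames)]
      e <- exp(2 * (sm - mean(sm)))   # depth 2: movie-locked modulation must
      env[c, ] <- e / mean(e)         # dominate per-frame Poisson noise
    }
    env
  })
}

#' Simulate firing rates of a synthetic population
#'
#' Rate of neuron n at frame t is
#' `baseline + jitter * gain_factor * tuning_gain_n * f_vm(theta_c - pref_n) * env_c(t)`
#' during ON frames of a condition-c presentation, plus a linear behavioral
#' term (weights times z-scored running/pupil) and a shared latent term,
#' clipped at zero. The per-presentation jitter is log-normal with mean 1 and
#' log-SD `trial_noise_sd`. For grating sessions the within-presentation
#' envelope is flat; for movie sessions each clip carries a fixed smooth
#' temporal envelope so repeated trials share a time course.
#'
#' @param truth a `ground_truth` from [make_population()].
#' @param protocol a `stim_protocol`.
#' @param behavior data.frame from [simulate_behavior()] with `n_frames` rows.
#' @param config the [sim_config()].
#' @return neurons x frames rate matrix (Hz), nonnegative.
#' @export
simulate_rates <- function(truth, protocol, behavior, config) {
  n <- config$n_neurons
  n_frames <- attr(protocol, "n_frames")
  if (nrow(behavior) != n_frames) {
    stop("behavior length (", nrow(behavior),
         ") does not match protocol span (", n_frames, ")")
  }
  stopifnot(length(truth$preferred_direction) == n)
  n_cond <- attr(protocol, "n_conditions")
  kind <- attr(protocol, "kind")

  rate <- matrix(config$baseline_rate_hz, n, n_frames)

  # behavioral drive (z-scored covariates, linear weights)
  zb <- scale(as.matrix(behavior))
  zb[is.nan(zb)] <- 0
  rate <- rate + truth$behavior_weights %*% t(zb)

  with_seed(derive_seed(config$seed, 3L), {
    # shared latent variability: AR(1) factors, unit stationary variance
    if (ncol(truth$latent_loadings) > 0) {
      rho <- 0.9
      z <- matrix(rnorm(ncol(truth$latent_loadings) * n_frames,
                        sd = sqrt(1 - rho^2)),
                  ncol(truth$latent_loadings), n_frames)
      for (t in 2:n_frames) z[, t] <- rho * z[, t - 1] + z[, t]
      rate <- rate + truth$latent_loadings %*% z
    }

    if (nrow(protocol) > 0) {
      angles <- if (kind == "gratings") seq(0, 315, by = 45)
                else seq(0, by = 360 / n_cond, length.out = n_cond)
      # neuron x condition evoked amplitude (Hz)
      amp <- outer(seq_len(n), seq_len(n_cond), function(i, c) {
        truth$tuning_gain[i] *
          von_mises_tuning(angles[c] - truth$preferred_direction[i],
                           config$tuning_kappa)
      })
      env <- if (kind == "movies") {
        clip_envelopes(n_cond, protocol$duration_frames[1],
                       derive_seed(config$seed, 4L))
      } else NULL
      sdl <- config$trial_noise_sd
      for (p in seq_len(nrow(protocol))) {
        c_id <- protocol$label[p] + 1L
        fr <- protocol$onset_frame[p] + seq_len(protocol$duration_frames[p]) - 1L
        jit <- rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
        ev <- (jit * config$gain_factor * amp[, c_id]) %o%
          (if (is.null(env)) rep(1, length(fr)) else env[c_id, ])
        rate[, fr] <- rate[, fr] + ev
      }
    }
  })
  pmax(rate, 0)
}

#' Draw spike counts from a rate matrix
#'
#' Inhomogeneous Poisson at frame resolution: counts with mean
#' `rate / frame_rate_hz` per frame.
#'
#' @param rates neurons x frames nonnegative rate matrix (Hz).
#' @param frame_rate_hz frame rate in Hz.
#' @param seed integer seed.
#' @return neurons x frames matrix of nonnegative integer counts.
#' @export
spikes_from_rates <- function(rates, frame_rate_hz = 16, seed = 1L) {
  if (any(rates < 0)) stop("rates must be nonnegative")
  stopifnot(frame_rate_hz > 0)
  with_seed(seed, {
    matrix(rpois(length(rates), lambda = rates / frame_rate_hz),
           nrow(rates), ncol(rates))
  })
}

#' Synthesize raw and neuropil fluorescence from spike counts
#'
#' Each event adds `spike_amplitude` units to a calcium trace decaying as
#' `exp(-dt / calcium_tau_s)`; the raw trace is a constant baseline plus the
#' calcium trace plus a per-neuron share of a common slow neuropil signal
#' plus white Gaussian noise. The neuropil signal is emitted separately (with
#' small independent measurement noise) so downstream neuropil correction is
#' a meaningful, imperfect inversion: per-neuron coupling is jittered around
#' `neuropil_coupling`.
#'
#' @param events neurons x frames nonnegative event counts/amplitudes.
#' @param config the [sim_config()].
#' @param seed integer seed (default derived from `config$seed`).
#' @return A [pop_recording] (without behavior attached).
#' @export
fluorescence_from_spikes <- function(events, config, seed = NULL) {
  if (any(events < 0)) stop("events must be nonnegative")
  if (config$calcium_tau_s <= 0) stop("calcium_tau_s must be > 0")
  n <- nrow(events); n_frames <- ncol(events)
  gam <- exp(-1 / (config$calcium_tau_s * config$frame_rate_hz))
  seed <- seed %||% derive_seed(config$seed, 5L)
  with_seed(seed, {
    calcium <- t(apply(events * config$spike_amplitude, 1, function(e) {
      as.numeric(stats::filter(e, gam, method = "recursive"))
    }))
    if (n == 1L) calcium <- matrix(calcium, 1L)
    npil <- log_ou(n_frames, dt = 1 / config$frame_rate_hz,
                   mean_value = 20, sd_log = 0.25, tau_s = 2)
    coupling <- config$neuropil_coupling * runif(n, 0.8, 1.2)
    noise <- matrix(rnorm(n * n_frames, sd = config$noise_sd_fluo), n, n_frames)
    F_raw <- config$baseline_fluo + calcium +
      coupling %o% npil + noise
    F_neuropil <- rep(1, n) %o% npil +
      matrix(rnorm(n * n_frames, sd = config$noise_sd_fluo / 4), n, n_frames)
    pop_recording(F_raw, F_neuropil, config$frame_rate_hz)
  })
}

#' Population recording container
#'
#' Holds raw and neuropil fluorescence matrices (neurons x frames), the
#' frame rate, and optionally the behavioral covariates.
#'
#' @param F_raw,F_neuropil neurons x frames matrices of equal shape.
#' @param frame_rate_hz frame rate in Hz.
#' @param behavior optional data.frame with `running` and `pupil` columns,
#'   one row per frame.
#' @return An object of class `pop_recording`.
#' @export
pop_recording <- function(F_raw, F_neuropil, frame_rate_hz, behavior = NULL) {
  F_raw <- as.matrix(F_raw); F_neuropil <- as.matrix(F_neuropil)
  if (!all(dim(F_raw) == dim(F_neuropil))) {
    stop("F_raw and F_neuropil must have identical dimensions")
  }
  stopifnot(frame_rate_hz > 0)
  if (!is.null(behavior) && nrow(behavior) != ncol(F_raw)) {
    stop("behavior must have one row per frame")
  }
  structure(list(F_raw = F_raw, F_neuropil = F_neuropil,
                 frame_rate_hz = frame_rate_hz, behavior = behavior),
            class = "pop_recording")
}

#' @export
print.pop_recording <- function(x, ...) {
  cat(sprintf("<pop_recording> %d neurons x %d frames @ %g Hz%s\n",
              nrow(x$F_raw), ncol(x$F_raw), x$frame_rate_hz,
              if (is.null(x$behavior)) "" else " (+behavior)"))
  invisible(x)
}

#' Simulate a complete synthetic imaging session
#'
#' Chains protocol construction, ground-truth sampling, behavior, rates,
#' Poisson spiking and fluorescence synthesis; every stage is seeded
#' deterministically from `config$seed`.
#'
#' @param kind session type passed to [make_protocol()].
#' @param config a [sim_config()].
#' @return A `synthetic_session` list with elements `recording`
#'   ([pop_recording] including behavior), `protocol`, `truth`, `config`,
#'   and the intermediate ground-truth signals `rates` and `spikes`.
#' @examples
#' s <- simulate_session("gratings", sim_config(10, "control", seed = 7))
#' s
#' @export
simulate_session <- function(kind, config) {
  protocol <- make_protocol(kind, config$frame_rate_hz)
  truth <- make_population(config)
  behavior <- simulate_behavior(attr(protocol, "n_frames"),
                                config$frame_rate_hz,
                                seed = derive_seed(config$seed, 2L))
  rates <- simulate_rates(truth, protocol, behavior, config)
  spikes <- spikes_from_rates(rates, config$frame_rate_hz,
                              seed = derive_seed(config$seed, 6L))
  rec <- fluorescence_from_spikes(spikes, config)
  rec$behavior <- behavior
  structure(list(recording = rec, protocol = protocol, truth = truth,
                 config = config, rates = rates, spikes = spikes),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %s, %s\n", x$config$condition,
              attr(x$protocol, "kind")))
  print(x$recording)
  invisible(x)
}
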