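test_that("population ground truth honors the class fractions", {
  cfg <- sim_config(40, "control", frac_tuned = 1, frac_behavior_coupled = 0,
                    frac_noise = 0, seed = 2)
  tr <- make_population(cfg)
  expect_true(all(tr$is_tuned))
  expect_true(all(tr$tuning_gain > 0))
  expect_true(all(tr$preferred_direction %in% seq(0, 315, by = 45)))

  cfg0 <- sim_config(40, "control", frac_tuned = 0, frac_behavior_coupled = 0,
                     frac_noise = 0, seed = 2)
  tr0 <- make_population(cfg0)
  expect_true(all(tr0$tuning_gain == 0))
  expect_true(all(tr0$behavior_weights == 0))
})

test_that("ground truth is deterministic in the seed", {
  cfg <- sim_config(25, "knockout", seed = 9)
  expect_identical(make_population(cfg), make_population(cfg))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(10, frac_tuned = 0.8, frac_behavior_coupled = 0.5),
               "fractions")
  expect_error(sim_config(10, frame_rate_hz = 0), "frame_rate_hz")
  expect_error(sim_config(10, calcium_tau_s = -1), "calcium_tau_s")
})

test_that("behavior series are positive, slow, and seed-deterministic", {
  b1 <- simulate_behavior(5000, 16, seed = 3)
  b2 <- simulate_behavior(5000, 16, seed = 3)
  expect_identical(b1, b2)
  expect_true(all(b1$running > 0) && all(b1$pupil > 0))

  const <- simulate_behavior(1000, 16, seed = 3,
                             running_sd_log = 0, pupil_sd_log = 0)
  expect_equal(length(unique(const$running)), 1)
  expect_equal(length(unique(const$pupil)), 1)
  expect_equal(const$running[1], 5, tolerance = 1e-12)
  expect_equal(const$pupil[1], 2, tolerance = 1e-12)

  ac1 <- mean(vapply(1:50, function(s) {
    p <- simulate_behavior(3000, 16, seed = s)$pupil
    cor(p[-1], p[-length(p)])
  }, numeric(1)))
  expect_gt(ac1, 0.9)
})

test_that("rates reduce to baseline without tuning, behavior, or latent", {
  cfg <- sim_config(5, "control", frac_tuned = 0, frac_behavior_coupled = 0,
                    frac_noise = 0, latent_dim = 0, seed = 4)
  proto <- make_protocol("gratings", 16)
  beh <- simulate_behavior(attr(proto, "n_frames"), 16, seed = 4)
  r <- simulate_rates(make_population(cfg), proto, beh, cfg)
  expect_equal(dim(r), c(5, attr(proto, "n_frames")))
  expect_true(all(r == cfg$baseline_rate_hz))
})

test_that("preferred/orthogonal rate contrast grows with tuning kappa", {
  proto <- make_protocol("gratings", 16)
  ratios <- vapply(c(0.5, 1, 2, 4), function(kap) {
    cfg <- sim_config(1, "control", frac_tuned = 1, frac_behavior_coupled = 0,
                      frac_noise = 0, latent_dim = 0, trial_noise_sd = 0,
                      tuning_kappa = kap, seed = 6)
    truth <- make_population(cfg)
    truth$preferred_direction <- 0
    beh <- simulate_behavior(attr(proto, "n_frames"), 16, seed = 6)
    r <- simulate_rates(truth, proto, beh, cfg)
    lab <- frame_labels(proto)
    ev <- function(d) mean(r[1, which(lab == d)]) - cfg$baseline_rate_hz
    ev(0) / ev(2)   # preferred (0 deg) vs orthogonal (90 deg)
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("evoked rate scales exactly linearly with gain_factor", {
  proto <- make_protocol("gratings", 16)
  mk <- function(g) {
    cfg <- sim_config(20, "control", frac_tuned = 1, frac_behavior_coupled = 0,
                      frac_noise = 0, latent_dim = 0, gain_factor = g,
                      seed = 8)
    beh <- simulate_behavior(attr(proto, "n_frames"), 16, seed = 8)
    list(r = simulate_rates(make_population(cfg), proto, beh, cfg), cfg = cfg)
  }
  a <- mk(1.0); b <- mk(0.6)
  expect_equal(b$r - b$cfg$baseline_rate_hz,
               0.6 * (a$r - a$cfg$baseline_rate_hz), tolerance = 1e-12)
})

test_that("spike counts are Poisson at rate/frame_rate", {
  expect_true(all(spikes_from_rates(matrix(0, 3, 100), 16, seed = 1) == 0))
  expect_error(spikes_from_rates(matrix(-1, 1, 10), 16), "nonnegative")

  r <- matrix(16, 1, 1e4)
  s <- spikes_from_rates(r, 16, seed = 2)
  se <- sqrt(1 / 1e4)                      # Poisson SE of the mean at mu = 1
  expect_lt(abs(mean(s) - 1), 3 * se)
  expect_lt(abs(var(as.numeric(s)) / mean(s) - 1), 0.1)  # Fano ~ 1
  expect_identical(s, spikes_from_rates(r, 16, seed = 2))
})

test_that("fluorescence follows the exponential kernel exactly when noiseless", {
  cfg <- sim_config(1, "control", noise_sd_fluo = 0, neuropil_coupling = 0,
                    calcium_tau_s = 0.5, seed = 3)
  ev <- matrix(0, 1, 64); ev[1, 10] <- 1
  rec <- fluorescence_from_spikes(ev, cfg)
  trace <- rec$F_raw[1, ] - cfg$baseline_fluo
  gam <- exp(-1 / (0.5 * 16))
  expect_equal(trace[10 + 0:20], cfg$spike_amplitude * gam^(0:20),
               tolerance = 1e-12)
  expect_true(all(trace[1:9] == 0))
  # kernel mass: geometric series sum, within discretization error of
  # amplitude * tau * frame_rate
  expect_equal(sum(trace), cfg$spike_amplitude * (1 - gam^55) / (1 - gam),
               tolerance = 1e-9)
  expect_lt(abs(sum(trace) - cfg$spike_amplitude * 0.5 * 16) /
              (cfg$spike_amplitude * 0.5 * 16), 0.07)

  rec0 <- fluorescence_from_spikes(matrix(0, 1, 64), cfg)
  expect_true(all(rec0$F_raw == cfg$baseline_fluo))
  cfg_bad <- cfg
  cfg_bad$calcium_tau_s <- 0
  expect_error(fluorescence_from_spikes(ev, cfg_bad), "tau")
})

test_that("spike trains decorrelate without shared latent or behavior", {
  r <- matrix(2, 20, 1e5)
  s <- spikes_from_rates(r, 16, seed = 12)
  C <- cor(t(s))
  expect_lt(abs(mean(C[upper.tri(C)])), 0.01)
})

test_that("full sessions are reproducible and internally consistent", {
  cfg <- sim_config(8, "knockout", seed = 13)
  s1 <- simulate_session("gratings", cfg)
  s2 <- simulate_session("gratings", cfg)
  expect_identical(s1$recording$F_raw, s2$recording$F_raw)
  expect_equal(ncol(s1$recording$F_raw), attr(s1$protocol, "n_frames"))
  expect_equal(nrow(s1$recording$behavior), attr(s1$protocol, "n_frames"))
  expect_equal(length(s1$truth$tuning_gain), 8)
})
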