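test_that("trial tensors align responses to the protocol window", {
  proto <- make_protocol("gratings", 16)
  n_frames <- attr(proto, "n_frames")

  tt_const <- build_trial_tensor(matrix(3.5, 2, n_frames), proto, 2)
  expect_equal(dim(tt_const$values), c(2, 8, 16))
  expect_true(all(tt_const$values == 3.5))

  # a single noiseless calcium transient at one onset: window mean equals
  # the partial geometric sum of the kernel divided by the window length
  gam <- exp(-1 / (0.5 * 16))
  tr <- matrix(0, 1, n_frames)
  on1 <- proto$onset_frame[1]
  tr[1, on1:(on1 + 31)] <- 2 * gam^(0:31)
  tt <- build_trial_tensor(tr, proto, 2)
  expect_equal(tt$values[1, 1, 1], 2 * (1 - gam^32) / (1 - gam) / 32,
               tolerance = 1e-9)
  expect_equal(tt$values[1, 2, 1], 0)
})

test_that("responsiveness requires condition dependence plus evoked excess", {
  flat <- tensor_from_array(array(1, c(1, 8, 16)))
  expect_false(classify_visually_responsive(flat, matrix(1, 1, 128)))

  s <- fix_ctl_small()
  tt <- build_trial_tensor(s$dff, s$session$protocol, 2)
  bl <- blank_responses(s$dff, s$session$protocol, 2)
  resp <- classify_visually_responsive(tt, bl)
  strong <- s$session$truth$is_tuned & s$session$truth$tuning_gain > 4
  expect_true(all(resp[strong]))
})

test_that("responsiveness false-positive rate is calibrated on null neurons", {
  set.seed(99)
  n_sim <- 2000
  vals <- array(rnorm(n_sim * 8 * 16), c(n_sim, 8, 16))
  blank <- matrix(rnorm(n_sim * 128), n_sim, 128)
  flags <- classify_visually_responsive(tensor_from_array(vals), blank)
  expect_lte(mean(flags), 0.015)
})

test_that("tuning extraction finds preferred direction, max response, ties", {
  v <- array(0, c(1, 8, 4)); v[1, 4, ] <- 10
  tun <- compute_tuning(tensor_from_array(v))
  expect_equal(tun$neurons$preferred_direction, 3)   # 0-based
  expect_equal(tun$neurons$max_response, 10)
  expect_equal(tun$neurons$preferred_orientation, 3)
  expect_equal(tun$centered[1, 5], 10)               # re-centered on preferred

  flat <- compute_tuning(tensor_from_array(array(2, c(1, 8, 4))))
  expect_equal(flat$neurons$preferred_direction, 0)  # tie -> lowest index
  expect_true(flat$neurons$flat)
  expect_equal(flat$neurons$osi, 0)
})

test_that("preferred directions are recovered for tuned neurons at default SNR", {
  cfg <- sim_config(200, "control", frac_tuned = 1, frac_behavior_coupled = 0,
                    frac_noise = 0, seed = 23)
  s <- simulate_session("gratings", cfg)
  tt <- build_trial_tensor(compute_dff(s$recording), s$protocol, 2)
  tun <- compute_tuning(tt)
  hit <- (tun$neurons$preferred_direction * 45) == s$truth$preferred_direction
  expect_gte(mean(hit), 0.95)
})

test_that("OSI formula cases and invariances hold", {
  expect_equal(compute_osi(c(10, 0, 0, 0, 10, 0, 0, 0)), 1.0)
  expect_equal(compute_osi(rep(4, 8)), 0.0)
  expect_equal(compute_osi(c(6, 0, 2, 0, 6, 0, 2, 0)), 0.5)
  expect_equal(compute_osi(rep(0, 8)), 0)
  set.seed(3)
  for (i in 1:20) {
    curve <- runif(8)
    expect_equal(compute_osi(curve * 7.3), compute_osi(curve),
                 tolerance = 1e-12)
    expect_gte(compute_osi(curve), 0)
    expect_lte(compute_osi(curve), 1)
  }
})

test_that("reliability index is the mean over all trial-pair correlations", {
  tm <- matrix(rep(c(1, 3, 2, 5), 3), 3, 4, byrow = TRUE)
  expect_equal(as.numeric(reliability_index(tm)), 1.0)
  anti <- rbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(as.numeric(reliability_index(anti)), -1.0)

  # 4-trial toy equals the enumerated C(4,2) mean
  set.seed(11)
  X <- matrix(rnorm(4 * 10), 4, 10)
  pairs <- combn(4, 2)
  oracle <- mean(apply(pairs, 2, function(ij) cor(X[ij[1], ], X[ij[2], ])))
  expect_equal(as.numeric(reliability_index(X)), oracle, tolerance = 1e-12)

  # independent white-noise trials average to ~0
  m <- vapply(1:100, function(s) {
    set.seed(s)
    as.numeric(reliability_index(matrix(rnorm(32 * 32), 32, 32)))
  }, numeric(1))
  expect_gt(mean(m), -0.05); expect_lt(mean(m), 0.05)

  # zero-variance trials: pair skipped, counted
  z <- rbind(rep(1, 5), rnorm(5), rnorm(5))
  r <- reliability_index(z)
  expect_equal(attr(r, "n_skipped"), 2)

  # affine per-trial transforms leave it unchanged
  set.seed(12)
  A <- matrix(rnorm(3 * 8), 3, 8)
  A2 <- A * c(2, 5, 0.3) + c(-1, 4, 10)
  expect_equal(as.numeric(reliability_index(A2)),
               as.numeric(reliability_index(A)), tolerance = 1e-12)
})

test_that("pairwise correlations cover all pairs and exclude constants", {
  set.seed(4)
  base <- rnorm(1000)
  mat <- rbind(base, 2 * base, rnorm(1000))
  cs <- pairwise_correlation(mat)
  expect_equal(length(cs$values), 3)
  expect_equal(cs$pairs$r[cs$pairs$i == 1 & cs$pairs$j == 2], 1.0)

  mat2 <- rbind(rnorm(1000), rep(1, 1000), rnorm(1000))
  cs2 <- pairwise_correlation(mat2)
  expect_equal(cs2$n_excluded, 1)
  expect_true(is.na(cs2$pairs$r[cs2$pairs$i == 2][1]))

  big <- matrix(rnorm(20 * 1e5), 20)
  expect_lt(abs(mean(pairwise_correlation(big)$values)), 0.02)
})

test_that("signal correlations reflect tuning similarity", {
  curve0 <- exp(2 * (cos((0:7) * 45 * pi / 180) - 1))
  curve90 <- exp(2 * (cos(((0:7) * 45 - 90) * pi / 180) - 1))
  v <- array(0, c(3, 8, 2))
  v[1, , ] <- curve0; v[2, , ] <- 3 * curve0; v[3, , ] <- curve90
  cs <- signal_correlation(tensor_from_array(v))
  expect_equal(cs$pairs$r[1], 1.0, tolerance = 1e-12)   # identical tuning
  expect_lt(cs$pairs$r[2], 0)                           # orthogonal tuning

  # label shuffling of one neuron destroys the correlation in expectation
  set.seed(5)
  r_shuf <- vapply(1:200, function(i) {
    vs <- v
    vs[2, , ] <- vs[2, sample(8), ]
    signal_correlation(tensor_from_array(vs))$pairs$r[1]
  }, numeric(1))
  expect_lt(abs(mean(r_shuf)), 0.1)
})

test_that("noise correlations track shared trial variability, not tuning", {
  # shared multiplicative jitter raises noise correlation monotonically
  mean_nc <- vapply(c(0.05, 0.2, 0.5), function(sdj) {
    set.seed(42)
    mean(vapply(1:30, function(i) {
      jit <- matrix(rlnorm(8 * 12, 0, sdj), 8, 12)
      v <- array(0, c(2, 8, 12))
      v[1, , ] <- 5 * jit * exp(rnorm(96, 0, 0.05))
      v[2, , ] <- 3 * jit * exp(rnorm(96, 0, 0.05))
      noise_correlation(tensor_from_array(v))$pairs$r[1]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_nc) > 0))

  # independent noise: mean near zero across many pairs
  set.seed(6)
  v <- array(rnorm(33 * 8 * 16), c(33, 8, 16))
  expect_lt(abs(mean(noise_correlation(tensor_from_array(v))$values)), 0.02)

  # tuned but independent neurons: signal correlation 1, noise ~ 0
  curve <- exp(2 * (cos((0:7) * 45 * pi / 180) - 1))
  set.seed(7)
  nc <- vapply(1:50, function(i) {
    v2 <- array(0, c(2, 8, 16))
    v2[1, , ] <- 10 * curve + rnorm(128, 0, 0.5)
    v2[2, , ] <- 10 * curve + rnorm(128, 0, 0.5)
    noise_correlation(tensor_from_array(v2))$pairs$r[1]
  }, numeric(1))
  expect_lt(abs(mean(nc)), 0.05)
})

test_that("noise correlation matches a hand z-scored computation", {
  v <- array(0, c(2, 2, 3))
  v[1, 1, ] <- c(1, 2, 3); v[1, 2, ] <- c(4, 6, 5)
  v[2, 1, ] <- c(2, 1, 3); v[2, 2, ] <- c(9, 7, 8)
  z <- function(x) (x - mean(x)) / sd(x)
  hand <- cor(c(z(v[1, 1, ]), z(v[1, 2, ])), c(z(v[2, 1, ]), z(v[2, 2, ])))
  cs <- noise_correlation(tensor_from_array(v))
  expect_equal(cs$pairs$r[1], hand, tolerance = 1e-12)
})
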