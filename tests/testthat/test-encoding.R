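# small dense design with exact glmnet-internal scale: columns mean 0,
# sum(x^2) = n, mutually orthogonal -- the soft-threshold closed form applies
orthonormal_design <- function(n = 200, p = 5) {
  M <- scale(matrix(rnorm(n * p), n, p), center = TRUE, scale = FALSE)
  qr.Q(qr(M)) * sqrt(n)   # columns: mean 0, sum(x^2) = n, orthogonal
}

test_that("design matrix has one indicator column per direction and lag", {
  proto <- make_protocol("gratings", 16)
  beh <- simulate_behavior(attr(proto, "n_frames"), 16, seed = 1)
  dm <- build_design_matrix(proto, beh, window_s = 2)
  expect_equal(ncol(dm$X), 8 * 32 + 2)
  expect_equal(sum(dm$group == "stimulus"), 256)
  expect_equal(sum(dm$continuous), 2)

  # column (dir 0, lag 5) is 1 exactly at frames onset+5 of dir-0 presentations
  col <- which(dm$label == "dir0_lag5")
  onsets <- proto$onset_frame[proto$label == 0]
  expect_equal(which(dm$X[, col] == 1), onsets + 5L)
  expect_equal(sum(dm$X[, col]), 16)

  # behavior columns are z-scored
  expect_equal(mean(dm$X[, ncol(dm$X)]), 0, tolerance = 1e-12)
  expect_equal(sd(dm$X[, ncol(dm$X)]), 1, tolerance = 1e-9)
})

test_that("constant behavioral covariates are dropped with a warning", {
  proto <- make_protocol("gratings", 16)
  beh <- data.frame(running = rnorm(attr(proto, "n_frames")),
                    pupil = rep(2, attr(proto, "n_frames")))
  expect_warning(dm <- build_design_matrix(proto, beh), "constant")
  expect_false("pupil" %in% dm$label)
  expect_true("running" %in% dm$label)
})

test_that("lasso weights match the soft-threshold closed form", {
  set.seed(8)
  X <- orthonormal_design(200, 5)
  beta_true <- c(2, -1.5, 0.8, 0, 0)
  y <- as.numeric(X %*% beta_true) + rnorm(200, sd = 0.3)
  lambda <- 0.2
  fit <- fit_lasso_glm(X, y, lambda = lambda, n_folds = 5)
  ols <- as.numeric(crossprod(X, y - mean(y))) / 200
  soft <- sign(ols) * pmax(abs(ols) - lambda, 0)
  expect_lt(max(abs(unname(fit$weights) - soft)), 1e-6)
})

test_that("lasso limits: interpolation at lambda 0, null model at huge lambda", {
  set.seed(9)
  X <- matrix(rnorm(200 * 5), 200, 5)
  y <- as.numeric(X %*% c(1, -2, 0.5, 3, -1))
  fit0 <- fit_lasso_glm(X, y, lambda = 0, n_folds = 10)
  expect_equal(fit0$r2_full, 1, tolerance = 1e-6)

  fitb <- fit_lasso_glm(X, y + rnorm(200), lambda = 1e6, n_folds = 10)
  expect_true(all(fitb$weights == 0))
  expect_lte(fitb$r2_full, 0)

  expect_error(fit_lasso_glm(X, y, lambda = -1), "lambda")
  const <- fit_lasso_glm(X, rep(2, 200))
  expect_true(const$flagged)
  expect_equal(const$r2_full, 0)
})

test_that("partial-model refits attribute variance to the right groups", {
  proto <- make_protocol("gratings", 4)
  beh <- simulate_behavior(attr(proto, "n_frames"), 4, seed = 2)
  dm <- build_design_matrix(proto, beh, window_s = 2)

  # stimulus-only neuron: behavior groups must not be significant
  set.seed(21)
  w <- rnorm(sum(dm$group == "stimulus"), 0, 0.05) + 0.1
  y_stim <- as.numeric(dm$X[, dm$group == "stimulus"] %*% w) +
    rnorm(nrow(dm$X), sd = 0.1)
  fit <- fit_lasso_glm(dm, y_stim)
  pt <- partial_model_test(dm, y_stim, fit)
  expect_true(pt$significant[pt$group == "stimulus"])
  expect_false(any(pt$significant[pt$group %in% c("pupil", "running")]))

  # pupil-driven neuron: pupil flagged in nearly all repetitions
  pup <- as.numeric(dm$X[, dm$label == "pupil"])
  hits <- vapply(1:25, function(i) {
    set.seed(400 + i)
    y <- 0.5 * pup + rnorm(length(pup), sd = 0.5)
    f <- fit_lasso_glm(dm, y)
    p <- partial_model_test(dm, y, f)
    p$significant[p$group == "pupil"]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("encoder proportions aggregate per-group significance", {
  mk <- function(sig) data.frame(group = c("stimulus", "pupil", "running"),
                                 significant = sig)
  allsig <- encoder_proportions(list(mk(c(TRUE, TRUE, TRUE)),
                                     mk(c(TRUE, TRUE, TRUE))))
  expect_true(all(allsig$fraction == 1))
  none <- encoder_proportions(list(mk(c(FALSE, FALSE, FALSE))))
  expect_true(all(none$fraction == 0))
  mix <- encoder_proportions(list(mk(c(TRUE, FALSE, FALSE)),
                                  mk(c(TRUE, TRUE, FALSE)),
                                  mk(c(FALSE, FALSE, FALSE))))
  expect_equal(mix$fraction[mix$group == "stimulus"], 2 / 3)
  expect_equal(mix$fraction[mix$group == "pupil"], 1 / 3)
})

test_that("population GLM identifies a copied predictor neuron", {
  set.seed(31)
  mat <- matrix(rnorm(12 * 800), 12, 800)
  mat[1, ] <- mat[5, ] + rnorm(800, sd = 0.01)
  fit <- population_glm(mat, target = 1, k = 11, seed = 2, n_samples = 1)
  expect_gt(fit$r2, 0.95)
  expect_equal(fit$weight_bin, "above 0.1")
  expect_gt(fit$max_weight, 0.5)
  expect_error(population_glm(mat, target = 1, k = 12), "smaller")
})

test_that("population GLM stays at chance for independent targets", {
  set.seed(32)
  mat <- matrix(rnorm(15 * 600), 15, 600)
  res <- vapply(1:20, function(s) {
    f <- population_glm(mat, target = 1, k = 10, seed = s, n_samples = 1)
    c(f$r2, f$max_weight)
  }, numeric(2))
  expect_gte(mean(res[1, ] <= 0.05), 0.9)
  expect_gte(mean(res[2, ] < 0.05), 0.9)
})

test_that("encoding fits are deterministic", {
  proto <- make_protocol("gratings", 4)
  beh <- simulate_behavior(attr(proto, "n_frames"), 4, seed = 3)
  dm <- build_design_matrix(proto, beh)
  set.seed(50); y <- rnorm(nrow(dm$X))
  f1 <- fit_lasso_glm(dm, y); f2 <- fit_lasso_glm(dm, y)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$r2_folds, f2$r2_folds)
})

test_that("population coupling is stronger in control than knockout sessions", {
  run <- function(cond, seed) {
    s <- simulate_session("gratings", sim_config(60, cond, seed = seed))
    dff <- compute_dff(s$recording)
    res <- vapply(1:15, function(t) {
      f <- population_glm(dff, t, k = 20, seed = 100 + t, n_samples = 2)
      c(f$r2, f$max_weight)
    }, numeric(2))
    c(r2 = mean(res[1, ]), mw = median(res[2, ]))
  }
  ctl <- run("control", 3)
  ko <- run("knockout", 53)
  expect_gt(ctl["r2"], ko["r2"] + 0.05)
  expect_gt(ctl["mw"], ko["mw"])
})
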