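#' Build the stimulus + behavior design matrix for encoding models
#'
#' One binary indicator column per (direction, frame lag) pair, lags covering
#' `window_s` seconds from stimulus onset (32 lags per direction at 16 Hz for
#' the default 2 s window): column (c, t_s) is 1 at frames `onset + t_s` of
#' every presentation of direction c. Overlapping presentations add (no
#' masking). Behavioral covariates (pupil, running) enter as one z-scored
#' continuous column each; a constant behavioral series is dropped with a
#' warning. Continuous columns are re-standardized on the training block
#' inside [fit_lasso_glm()].
#'
#' @param protocol a labeled `stim_protocol`.
#' @param behavior data.frame with `running` and `pupil`, one row per frame.
#' @param window_s stimulus lag window in seconds (default 2).
#' @return A `design_matrix`: sparse `X` (frames x predictors), `group`
#'   (per-column: `"stimulus"`, `"pupil"`, `"running"`), `label` (per-column
#'   fine id), `continuous` (logical per column), `frame_rate_hz`.
#' @export
build_design_matrix <- function(protocol, behavior, window_s = 2) {
  fs <- attr(protocol, "frame_rate_hz")
  n_frames <- attr(protocol, "n_frames")
  if (nrow(protocol) == 0) stop("protocol has no labeled presentations")
  if (nrow(behavior) != n_frames) stop("behavior length mismatch")
  n_cond <- attr(protocol, "n_conditions")
  n_lags <- as.integer(round(window_s * fs))

  rows <- integer(0); cols <- integer(0)
  for (p in seq_len(nrow(protocol))) {
    fr <- protocol$onset_frame[p] + 0:(n_lags - 1L)
    ok <- fr <= n_frames
    col0 <- protocol$label[p] * n_lags
    rows <- c(rows, fr[ok])
    cols <- c(cols, col0 + which(ok))
  }
  X_stim <- Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                                 dims = c(n_frames, n_cond * n_lags))
  lab_stim <- paste0("dir", rep(seq_len(n_cond) - 1L, each = n_lags),
                     "_lag", rep(seq_len(n_lags) - 1L, n_cond))

  beh_cols <- list(); beh_lab <- character(0); beh_grp <- character(0)
  for (nm in c("pupil", "running")) {
    v <- behavior[[nm]]
    if (sd(v) == 0) {
      warning("behavior column '", nm, "' is constant; dropped")
      next
    }
    beh_cols[[nm]] <- as.numeric(scale(v))
    beh_lab <- c(beh_lab, nm); beh_grp <- c(beh_grp, nm)
  }
  X <- if (length(beh_cols)) {
    cbind(X_stim, Matrix::Matrix(do.call(cbind, beh_cols), sparse = TRUE))
  } else X_stim
  group <- c(rep("stimulus", ncol(X_stim)), beh_grp)
  label <- c(lab_stim, beh_lab)
  continuous <- c(rep(FALSE, ncol(X_stim)), rep(TRUE, length(beh_lab)))

  nz <- Matrix::colSums(X != 0) > 0
  X <- X[, nz, drop = FALSE]
  structure(list(X = X, group = group[nz], label = label[nz],
                 continuous = continuous[nz], frame_rate_hz = fs,
                 window_s = window_s),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d frames x %d predictors (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s:%d", names(table(x$group)), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

# Contiguous temporal fold blocks (respects autocorrelation).
contiguous_folds <- function(n, n_folds) {
  split(seq_len(n), cut(seq_len(n), n_folds, labels = FALSE))
}

# One lasso fit + prediction. Predictors are standardized inside the solver
# (the default of the standard lasso implementations; without it the sparse
# 0/1 stimulus indicators are never selected at small lambda); weights are
# reported back on the original scale. lambda = 0 falls back to OLS.
lasso_fit_predict <- function(Xtr, ytr, Xte, lambda) {
  if (lambda == 0) {
    fit <- lm.fit(cbind(1, as.matrix(Xtr)), ytr)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    pred <- if (nrow(Xte)) as.numeric(cbind(1, as.matrix(Xte)) %*% beta)
            else numeric(0)
    list(beta = beta[-1], intercept = beta[1], pred = pred)
  } else {
    fit <- glmnet::glmnet(Xtr, ytr, alpha = 1, lambda = lambda,
                          standardize = TRUE, intercept = TRUE,
                          thresh = 1e-10, maxit = 1e6)
    pred <- if (nrow(Xte)) as.numeric(predict(fit, Xte)) else numeric(0)
    list(beta = as.numeric(fit$beta), intercept = as.numeric(fit$a0),
         pred = pred)
  }
}

heldout_r2 <- function(y_test, pred) {
  ss_tot <- sum((y_test - mean(y_test))^2)
  if (ss_tot == 0) return(0)
  1 - sum((y_test - pred)^2) / ss_tot
}

# Standardize designated continuous columns with training-block statistics.
standardize_cols <- function(X, continuous, train_idx) {
  if (!any(continuous)) return(X)
  for (j in which(continuous)) {
    mu <- mean(X[train_idx, j]); s <- sd(X[train_idx, j])
    if (s > 0) X[, j] <- (X[, j] - mu) / s
  }
  X
}

#' Cross-validated lasso encoding model for one neuron
#'
#' Minimizes `(1/2n) ||y - X b - intercept||^2 + lambda ||b||_1` on each
#' fold's training block (folds are contiguous temporal blocks) and scores
#' held-out `R^2 = 1 - SS_res / SS_tot` on the left-out block; `r2_full` is
#' the mean over folds. Continuous predictor columns are re-z-scored with
#' training-block statistics only. A final fit on all frames provides the
#' reported weights.
#'
#' @param design a `design_matrix` (or a plain matrix plus `groups`).
#' @param y the neuron's activity trace (length = frames).
#' @param lambda lasso penalty (default 1e-3).
#' @param n_folds number of cross-validation folds (default 10).
#' @param groups optional per-column group labels when `design` is a matrix.
#' @return An `encoding_fit`: `weights`, `intercept`, `r2_full`, `r2_folds`,
#'   `lambda`, `folds`, `flagged` (TRUE when `y` is constant).
#' @export
fit_lasso_glm <- function(design, y, lambda = 1e-3, n_folds = 10,
                          groups = NULL) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (inherits(design, "design_matrix")) {
    X <- design$X; groups <- design$group; continuous <- design$continuous
  } else {
    X <- design
    groups <- groups %||% rep("x", ncol(X))
    continuous <- rep(FALSE, ncol(X))
  }
  stopifnot(length(y) == nrow(X), all(is.finite(y)))
  flagged <- sd(y) == 0
  folds <- contiguous_folds(length(y), n_folds)
  r2_folds <- vapply(folds, function(test_idx) {
    if (flagged) return(0)
    train_idx <- setdiff(seq_along(y), test_idx)
    Xs <- standardize_cols(X, continuous, train_idx)
    f <- lasso_fit_predict(Xs[train_idx, , drop = FALSE], y[train_idx],
                           Xs[test_idx, , drop = FALSE], lambda)
    heldout_r2(y[test_idx], f$pred)
  }, numeric(1))
  full <- if (flagged) {
    list(beta = rep(0, ncol(X)), intercept = mean(y))
  } else {
    lasso_fit_predict(standardize_cols(X, continuous, seq_along(y)), y,
                      X[0, , drop = FALSE], lambda)
  }
  structure(list(weights = setNames(full$beta,
                                    if (inherits(design, "design_matrix"))
                                      design$label else colnames(X)),
                 intercept = full$intercept,
                 r2_full = mean(r2_folds), r2_folds = unname(r2_folds),
                 groups = groups, lambda = lambda, n_folds = n_folds,
                 flagged = flagged),
            class = "encoding_fit")
}

#' @export
print.encoding_fit <- function(x, ...) {
  cat(sprintf("<encoding_fit> %d predictors, lambda=%g, %d-fold CV: R2 = %.4f\n",
              length(x$weights), x$lambda, x$n_folds, x$r2_full))
  invisible(x)
}

#' Partial-model significance test per predictor group
#'
#' For every predictor group the model is refit with that group's columns
#' set to zero (the partial model) on the same contiguous folds, and the
#' fold-wise held-out `R^2` of full vs partial model are compared with a
#' paired two-sided t-test. P-values are Holm-corrected across the groups
#' tested for this neuron; a group is a significant encoder iff its corrected
#' p < `alpha` and the full model outperforms the partial one on average.
#'
#' @param design the `design_matrix` used for `fit`.
#' @param y the neuron's activity trace.
#' @param fit the [fit_lasso_glm()] result for this neuron.
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame (group, r2_full, r2_partial, t_stat, p_value, p_holm,
#'   significant).
#' @export
partial_model_test <- function(design, y, fit, alpha = 0.05) {
  if (fit$n_folds < 3) stop("need at least 3 folds")
  X <- design$X
  folds <- contiguous_folds(length(y), fit$n_folds)
  groups <- unique(design$group)
  res <- lapply(groups, function(g) {
    Xg <- X
    Xg[, design$group == g] <- 0
    r2p <- vapply(folds, function(test_idx) {
      train_idx <- setdiff(seq_along(y), test_idx)
      Xs <- standardize_cols(Xg, design$continuous & design$group != g,
                             train_idx)
      f <- lasso_fit_predict(Xs[train_idx, , drop = FALSE], y[train_idx],
                             Xs[test_idx, , drop = FALSE], fit$lambda)
      heldout_r2(y[test_idx], f$pred)
    }, numeric(1))
    d <- fit$r2_folds - r2p
    p <- if (sd(d) == 0) 1 else t.test(fit$r2_folds, r2p, paired = TRUE)$p.value
    data.frame(group = g, r2_full = mean(fit$r2_folds), r2_partial = mean(r2p),
               t_stat = if (sd(d) == 0) 0 else
                 unname(t.test(fit$r2_folds, r2p, paired = TRUE)$statistic),
               p_value = p)
  })
  out <- do.call(rbind, res)
  out$p_holm <- p.adjust(out$p_value, method = "holm")
  out$significant <- out$p_holm < alpha & out$r2_full > out$r2_partial
  out
}

#' Fraction of neurons significantly encoding each predictor group
#'
#' @param tests list of per-neuron [partial_model_test()] tables.
#' @return data.frame (group, n_significant, n_neurons, fraction).
#' @export
encoder_proportions <- function(tests) {
  stopifnot(length(tests) >= 1)
  tab <- do.call(rbind, lapply(seq_along(tests), function(i) {
    cbind(tests[[i]][, c("group", "significant")], neuron = i)
  }))
  agg <- aggregate(significant ~ group, tab, function(z) c(sum(z), length(z)))
  data.frame(group = agg$group,
             n_significant = agg$significant[, 1],
             n_neurons = agg$significant[, 2],
             fraction = agg$significant[, 1] / agg$significant[, 2])
}

#' Population-activity encoding model for one target neuron
#'
#' Predicts the target neuron's trace from `k` randomly sampled other
#' neurons' traces with the same lasso and contiguous 10-fold scheme;
#' repeated for `n_samples` random predictor sets and averaged. The target
#' trace is standardized once and the predictor traces are z-scored on each
#' training block, so weights are on a common SD-per-SD scale and the
#' 0.05 / 0.1 weight-magnitude bins are comparable across neurons. The
#' maximum (signed) predictor weight of the full-data fit is extracted and
#' binned at 0.05 and 0.1.
#'
#' @param traces neurons x frames activity matrix (or `dff_traces`).
#' @param target target neuron index.
#' @param k number of predictor neurons (< available neurons).
#' @param seed integer seed for predictor sampling.
#' @param lambda lasso penalty (default 1e-3).
#' @param n_folds folds (default 10).
#' @param n_samples random predictor sets to average over (default 10).
#' @param use_abs use the absolute maximum weight instead of the signed one.
#' @return A `pop_encoding_fit`: `r2`, `max_weight`, `weight_bin`,
#'   per-sample vectors, `target`, `k`.
#' @export
population_glm <- function(traces, target, k, seed = 1L, lambda = 1e-3,
                           n_folds = 10, n_samples = 10, use_abs = FALSE) {
  mat <- trace_matrix(traces)
  others <- setdiff(seq_len(nrow(mat)), target)
  if (k >= nrow(mat)) stop("k must be smaller than the number of neurons")
  y <- mat[target, ]
  if (sd(y) > 0) y <- as.numeric(scale(y))  # R^2 is scale-invariant; weights
                                            # become SD-per-SD for binning
  r2s <- numeric(n_samples); mw <- numeric(n_samples)
  with_seed(seed, {
    for (s in seq_len(n_samples)) {
      pred_ids <- sample(others, k)
      X <- t(mat[pred_ids, , drop = FALSE])
      fit <- fit_lasso_glm(
        structure(list(X = Matrix::Matrix(X, sparse = FALSE),
                       group = rep("population", k),
                       label = paste0("n", pred_ids),
                       continuous = rep(TRUE, k),
                       frame_rate_hz = NA, window_s = NA),
                  class = "design_matrix"),
        y, lambda = lambda, n_folds = n_folds)
      r2s[s] <- fit$r2_full
      mw[s] <- if (use_abs) max(abs(fit$weights)) else max(fit$weights)
    }
  })
  max_weight <- mean(mw)
  bin <- cut(max_weight, c(-Inf, 0.05, 0.1, Inf),
             labels = c("below 0.05", "0.05-0.1", "above 0.1"))
  structure(list(target = target, k = k, r2 = mean(r2s),
                 max_weight = max_weight, weight_bin = as.character(bin),
                 r2_samples = r2s, max_weight_samples = mw),
            class = "pop_encoding_fit")
}

#' @export
print.pop_encoding_fit <- function(x, ...) {
  cat(sprintf("<pop_encoding_fit> target %d, k=%d: R2 = %.4f, max weight %.4f (%s)\n",
              x$target, x$k, x$r2, x$max_weight, x$weight_bin))
  invisible(x)
}
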