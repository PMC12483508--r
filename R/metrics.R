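#' Trial-aligned response tensor
#'
#' Aligns a trace matrix to the protocol's presentations. For every
#' presentation the response is the mean trace value over the window starting
#' at stimulus onset; responses are arranged neuron x condition x trial in
#' presentation order. With `keep_time = TRUE` the unaveraged window time
#' courses are kept as a neuron x condition x trial x time array (needed for
#' the trial-to-trial reliability index).
#'
#' @param traces a `dff_traces`, `event_traces`, or neurons x frames matrix.
#' @param protocol a `stim_protocol` with labeled presentations.
#' @param window_s analysis window (s) from onset; defaults to the
#'   presentation duration; truncated with a warning if it runs past the end
#'   of the recording.
#' @param keep_time also keep the within-window time courses.
#' @return A `trial_tensor`: `values` (neuron x condition x trial),
#'   optionally `time_courses` (x time), `window_s`, `source`.
#' @export
build_trial_tensor <- function(traces, protocol, window_s = NULL,
                               keep_time = FALSE) {
  mat <- trace_matrix(traces)
  fs <- attr(protocol, "frame_rate_hz")
  if (nrow(protocol) == 0) stop("protocol has no labeled presentations")
  n_cond <- attr(protocol, "n_conditions")
  if (!all(0:(n_cond - 1L) %in% protocol$label)) {
    stop("protocol is missing one or more conditions")
  }
  window_s <- window_s %||% (protocol$duration_frames[1] / fs)
  win <- as.integer(round(window_s * fs))
  if (any(protocol$onset_frame + win - 1L > ncol(mat))) {
    win <- min(win, ncol(mat) - max(protocol$onset_frame) + 1L)
    warning("window truncated to ", win, " frames to fit the recording")
  }
  n <- nrow(mat)
  n_trials <- min(table(protocol$label))
  vals <- array(NA_real_, c(n, n_cond, n_trials))
  tc <- if (keep_time) array(NA_real_, c(n, n_cond, n_trials, win)) else NULL
  seen <- integer(n_cond)
  for (p in seq_len(nrow(protocol))) {
    c_id <- protocol$label[p] + 1L
    if (seen[c_id] >= n_trials) next
    seen[c_id] <- seen[c_id] + 1L
    fr <- protocol$onset_frame[p] + seq_len(win) - 1L
    seg <- mat[, fr, drop = FALSE]
    vals[, c_id, seen[c_id]] <- rowMeans(seg)
    if (keep_time) tc[, c_id, seen[c_id], ] <- seg
  }
  structure(list(values = vals, time_courses = tc,
                 window_s = win / fs, frame_rate_hz = fs,
                 source = class(traces)[1]),
            class = "trial_tensor")
}

trace_matrix <- function(traces) {
  if (inherits(traces, "dff_traces")) traces$dff
  else if (inherits(traces, "event_traces")) traces$events
  else as.matrix(traces)
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<trial_tensor> %d neurons x %d conditions x %d trials (window %g s%s)\n",
              d[1], d[2], d[3], x$window_s,
              if (is.null(x$time_courses)) "" else ", time courses kept"))
  invisible(x)
}

#' Blank (OFF-period) responses matched to each presentation
#'
#' For every labeled presentation, the mean trace value over the window of
#' the same length that ends immediately before stimulus onset (the OFF
#' period). Used as the baseline sample for the responsiveness test.
#'
#' @inheritParams build_trial_tensor
#' @return neurons x presentations matrix of blank responses.
#' @export
blank_responses <- function(traces, protocol, window_s = NULL) {
  mat <- trace_matrix(traces)
  fs <- attr(protocol, "frame_rate_hz")
  window_s <- window_s %||% (protocol$duration_frames[1] / fs)
  win <- as.integer(round(window_s * fs))
  out <- matrix(NA_real_, nrow(mat), nrow(protocol))
  for (p in seq_len(nrow(protocol))) {
    lo <- max(1L, protocol$onset_frame[p] - win)
    fr <- lo:(protocol$onset_frame[p] - 1L)
    out[, p] <- rowMeans(mat[, fr, drop = FALSE])
  }
  out
}

#' Classify neurons as visually responsive
#'
#' A neuron is visually responsive iff a one-way ANOVA of its single-trial
#' responses across the stimulus conditions plus the blank (OFF) condition is
#' significant at `alpha`, and the mean response of its best condition
#' exceeds the mean blank response.
#'
#' @param tensor a `trial_tensor` of evoked responses.
#' @param blank neurons x trials matrix of blank responses (see
#'   [blank_responses()]).
#' @param alpha significance level (default 0.01).
#' @return logical vector, one flag per neuron (`NA` for excluded neurons).
#' @export
classify_visually_responsive <- function(tensor, blank, alpha = 0.01) {
  vals <- tensor$values
  n <- dim(vals)[1]; n_cond <- dim(vals)[2]; n_trials <- dim(vals)[3]
  if (n_trials < 2) stop("need at least 2 trials per condition")
  grp <- factor(c(rep(seq_len(n_cond), each = n_trials),
                  rep(0L, ncol(blank))))
  vapply(seq_len(n), function(i) {
    y <- c(t(vals[i, , ]), blank[i, ])
    if (any(!is.finite(y))) return(NA)
    if (var(y) == 0) return(FALSE)
    p <- tryCatch(stats::oneway.test(y ~ grp, var.equal = TRUE)$p.value,
                  error = function(e) NA_real_)
    if (!is.finite(p)) return(FALSE)
    cond_means <- rowMeans(vals[i, , , drop = TRUE])
    p < alpha && max(cond_means) > mean(blank[i, ])
  }, logical(1))
}

#' Orientation selectivity index of an 8-direction tuning curve
#'
#' Responses are floored at zero, opposite directions are averaged into 4
#' orientations, and `OSI = (R_pref - R_orth) / (R_pref + R_orth)` where
#' `R_orth` is the orientation 90 degrees from the preferred one (ties break
#' to the lowest index). Clipped to \[0, 1\]; a curve with
#' `R_pref + R_orth = 0` returns 0.
#'
#' @param tuning_curve numeric vector of 8 mean responses (directions 45
#'   degrees apart).
#' @return scalar OSI in \[0, 1\].
#' @examples
#' compute_osi(c(10, 0, 0, 0, 10, 0, 0, 0))  # 1
#' compute_osi(rep(3, 8))                    # 0
#' @export
compute_osi <- function(tuning_curve) {
  stopifnot(length(tuning_curve) == 8)
  r <- pmax(tuning_curve, 0)
  ori <- (r[1:4] + r[5:8]) / 2
  pref <- which.max(ori)                 # which.max breaks ties to lowest index
  orth <- ((pref - 1L + 2L) %% 4L) + 1L  # orientation 90 deg away
  tot <- ori[pref] + ori[orth]
  if (tot == 0) return(0)
  min(max((ori[pref] - ori[orth]) / tot, 0), 1)
}

#' Tuning curves, preferred direction, OSI and maximum response
#'
#' For every neuron: the trial-mean (+/- SEM) response per direction, the
#' preferred direction (argmax, ties to the lowest index), the orientation
#' selectivity index, the maximum response (mean response at the preferred
#' direction), and the tuning curve re-centered on the preferred direction
#' for population averaging.
#'
#' @param tensor a `trial_tensor` over the 8 grating directions.
#' @return A `tuning_result`: data.frame `neurons` (preferred_direction,
#'   preferred_orientation — 0-based condition ids — osi, max_response,
#'   flat), matrices `tuning_curve`, `sem`, `centered` (neurons x 8).
#' @export
compute_tuning <- function(tensor) {
  vals <- tensor$values
  n <- dim(vals)[1]; n_cond <- dim(vals)[2]; n_trials <- dim(vals)[3]
  if (n_cond != 8) stop("tuning analysis expects 8 directions")
  tc <- apply(vals, c(1, 2), mean)
  sem <- apply(vals, c(1, 2), sd) / sqrt(n_trials)
  pref <- apply(tc, 1, which.max)
  centered <- t(vapply(seq_len(n), function(i) {
    tc[i, ((seq_len(n_cond) - 1L + (pref[i] - 1L) - 4L) %% n_cond) + 1L]
  }, numeric(n_cond)))
  osi <- apply(tc, 1, compute_osi)
  flat <- apply(tc, 1, function(r) all(r == r[1]))
  neurons <- data.frame(
    neuron = seq_len(n),
    preferred_direction = pref - 1L,
    preferred_orientation = (pref - 1L) %% 4L,
    osi = osi,
    max_response = tc[cbind(seq_len(n), pref)],
    flat = flat)
  structure(list(neurons = neurons, tuning_curve = tc, sem = sem,
                 centered = centered),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> %d neurons; median OSI %.3f, median max response %.4f\n",
              nrow(x$neurons), median(x$neurons$osi), median(x$neurons$max_response)))
  invisible(x)
}

#' Trial-to-trial reliability index
#'
#' Mean Pearson correlation over all pairs of repeated-trial response time
#' courses for one stimulus. Pairs involving a zero-variance trial are
#' skipped; the number of skipped pairs is reported as an attribute.
#'
#' @param trial_matrix trials x time matrix of one neuron's responses to one
#'   stimulus.
#' @return scalar mean pairwise correlation with attribute `n_skipped`.
#' @export
reliability_index <- function(trial_matrix) {
  stopifnot(nrow(trial_matrix) >= 2, ncol(trial_matrix) >= 2)
  C <- suppressWarnings(stats::cor(t(trial_matrix)))
  vals <- C[upper.tri(C)]
  ok <- is.finite(vals)
  structure(if (any(ok)) mean(vals[ok]) else NA_real_,
            n_skipped = sum(!ok))
}

#' Per-neuron reliability at the preferred stimulus
#'
#' The neuron-level reliability value is [reliability_index()] evaluated at
#' the neuron's preferred stimulus, defined as the condition with the highest
#' trial-mean response (ties to the lowest index).
#'
#' @param tensor a `trial_tensor` built with `keep_time = TRUE`.
#' @return data.frame (neuron, preferred_stimulus, reliability).
#' @export
reliability_per_neuron <- function(tensor) {
  if (is.null(tensor$time_courses)) {
    stop("tensor must be built with keep_time = TRUE")
  }
  vals <- tensor$values
  n <- dim(vals)[1]
  pref <- apply(apply(vals, c(1, 2), mean), 1, which.max)
  rel <- vapply(seq_len(n), function(i) {
    as.numeric(reliability_index(tensor$time_courses[i, pref[i], , ]))
  }, numeric(1))
  data.frame(neuron = seq_len(n), preferred_stimulus = pref - 1L,
             reliability = rel)
}

make_correlation_set <- function(R, kind, excluded) {
  vals <- R[upper.tri(R)]
  idx <- which(upper.tri(R), arr.ind = TRUE)
  structure(list(values = vals,
                 pairs = data.frame(i = idx[, 1], j = idx[, 2], r = vals),
                 kind = kind, n_excluded = length(excluded),
                 excluded = excluded),
            class = "correlation_set")
}

#' @export
print.correlation_set <- function(x, ...) {
  cat(sprintf("<correlation_set> %s: %d pairs, mean r = %.4f (%d neurons excluded)\n",
              x$kind, length(x$values), mean(x$values, na.rm = TRUE),
              x$n_excluded))
  invisible(x)
}

#' Pairwise activity correlations
#'
#' Pearson correlation between pairs of neurons' activity vectors. With a
#' protocol, each neuron's within-presentation activity is concatenated
#' across all presentations first; without one (spontaneous sessions) the
#' full traces are used. Constant neurons are excluded and reported.
#'
#' @param traces `event_traces` (the default source for spontaneous rates),
#'   `dff_traces`, or a matrix.
#' @param protocol optional `stim_protocol` to restrict to stimulus frames.
#' @param kind label stored on the result.
#' @return A `correlation_set` over the `n (n - 1) / 2` neuron pairs.
#' @export
pairwise_correlation <- function(traces, protocol = NULL,
                                 kind = "spontaneous") {
  mat <- trace_matrix(traces)
  if (!is.null(protocol) && nrow(protocol) > 0) {
    fr <- unlist(lapply(seq_len(nrow(protocol)), function(p) {
      protocol$onset_frame[p] + seq_len(protocol$duration_frames[p]) - 1L
    }))
    mat <- mat[, fr, drop = FALSE]
  }
  if (nrow(mat) < 2) stop("need at least 2 neurons")
  sds <- apply(mat, 1, sd)
  excluded <- which(!is.finite(sds) | sds == 0)
  keep <- setdiff(seq_len(nrow(mat)), excluded)
  R <- matrix(NA_real_, nrow(mat), nrow(mat))
  R[keep, keep] <- stats::cor(t(mat[keep, , drop = FALSE]))
  make_correlation_set(R, kind, excluded)
}

#' Signal correlations
#'
#' Pearson correlation between per-neuron trial-averaged condition response
#' vectors (tuning similarity). Neurons with a flat mean vector are excluded.
#'
#' @param tensor a `trial_tensor`.
#' @return A `correlation_set` of kind `"signal"`.
#' @export
signal_correlation <- function(tensor) {
  m <- apply(tensor$values, c(1, 2), mean)
  if (ncol(m) < 2) stop("need at least 2 conditions")
  sds <- apply(m, 1, sd)
  excluded <- which(!is.finite(sds) | sds == 0)
  keep <- setdiff(seq_len(nrow(m)), excluded)
  R <- matrix(NA_real_, nrow(m), nrow(m))
  R[keep, keep] <- stats::cor(t(m[keep, , drop = FALSE]))
  make_correlation_set(R, "signal", excluded)
}

#' Noise correlations
#'
#' Each neuron's trial responses are z-scored within every condition (mean 0,
#' SD 1 across trials), removing the tuning component; the z-scores are
#' concatenated across conditions and correlated between neurons. Conditions
#' where a neuron has zero trial variance are set to `NA` and dropped
#' pairwise.
#'
#' @param tensor a `trial_tensor` with >= 2 trials per condition.
#' @return A `correlation_set` of kind `"noise"`.
#' @export
noise_correlation <- function(tensor) {
  vals <- tensor$values
  n <- dim(vals)[1]; n_cond <- dim(vals)[2]; n_trials <- dim(vals)[3]
  if (n_trials < 2) stop("need at least 2 trials per condition")
  Z <- matrix(NA_real_, n, n_cond * n_trials)
  for (c_id in seq_len(n_cond)) {
    x <- vals[, c_id, , drop = TRUE]
    if (n == 1L) x <- matrix(x, 1L)
    mu <- rowMeans(x); s <- apply(x, 1, sd)
    z <- (x - mu) / s
    z[s == 0 | !is.finite(s), ] <- NA_real_
    Z[, (c_id - 1L) * n_trials + seq_len(n_trials)] <- z
  }
  R <- suppressWarnings(stats::cor(t(Z), use = "pairwise.complete.obs"))
  make_correlation_set(R, "noise", integer(0))
}
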