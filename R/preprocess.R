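#' Neuropil correction
#'
#' Subtracts a fixed fraction of the neuropil signal from the raw somatic
#' fluorescence: `F_roi = F_raw - coeff * F_neuropil`.
#'
#' @param rec a [pop_recording], or a raw matrix when `F_neuropil` is given.
#' @param coeff contamination coefficient in \[0,1\] (default 0.7).
#' @param F_neuropil optional neuropil matrix when `rec` is a plain matrix.
#' @return neurons x frames corrected fluorescence matrix.
#' @examples
#' neuropil_correct(matrix(100), coeff = 0.7, F_neuropil = matrix(40))  # 72
#' @export
neuropil_correct <- function(rec, coeff = 0.7, F_neuropil = NULL) {
  if (inherits(rec, "pop_recording")) {
    F_raw <- rec$F_raw; F_neuropil <- rec$F_neuropil
  } else {
    F_raw <- as.matrix(rec); F_neuropil <- as.matrix(F_neuropil)
  }
  if (!all(dim(F_raw) == dim(F_neuropil))) stop("matrix shapes differ")
  if (coeff < 0 || coeff > 1) stop("coeff must lie in [0,1]")
  F_raw - coeff * F_neuropil
}

#' Baseline fluorescence as the mode of the trace's value distribution
#'
#' Fits a Gaussian kernel density (Silverman's rule-of-thumb bandwidth) to
#' the fluorescence values of one trace on a 512-point grid spanning the data
#' range and returns the grid point of maximum density. Because active frames
#' are sparse relative to baseline frames, the density peak sits at the
#' resting fluorescence level.
#'
#' @param trace numeric fluorescence series (>= 100 frames recommended).
#' @return scalar baseline F0.
#' @export
estimate_f0 <- function(trace) {
  if (any(!is.finite(trace))) stop("trace contains non-finite values")
  rng <- range(trace)
  if (rng[1] == rng[2]) return(rng[1])
  d <- stats::density(trace, bw = "nrd0", n = 512, from = rng[1], to = rng[2])
  d$x[which.max(d$y)]
}

#' Compute dF/F traces
#'
#' Applies [neuropil_correct()], estimates a per-neuron baseline F0 with
#' [estimate_f0()], and returns `(F - F0) / F0`. Neurons whose baseline is
#' not strictly positive cannot be normalized; they are excluded (rows set to
#' `NA`) and reported.
#'
#' @param rec a [pop_recording].
#' @param coeff neuropil contamination coefficient.
#' @return A `dff_traces` object: `dff` (neurons x frames), `f0` (per
#'   neuron), `excluded` (neuron indices with nonpositive baseline),
#'   `frame_rate_hz`.
#' @export
compute_dff <- function(rec, coeff = 0.7) {
  corrected <- unname(neuropil_correct(rec, coeff))
  f0 <- unname(apply(corrected, 1, estimate_f0))
  bad <- which(!(f0 > 0))
  dff <- (corrected - f0) / f0
  if (length(bad)) {
    dff[bad, ] <- NA_real_
    message(length(bad), " neuron(s) excluded: nonpositive baseline F0 (",
            paste(bad, collapse = ", "), ")")
  }
  structure(list(dff = dff, f0 = f0, excluded = bad,
                 frame_rate_hz = rec$frame_rate_hz),
            class = "dff_traces")
}

#' @export
print.dff_traces <- function(x, ...) {
  cat(sprintf("<dff_traces> %d neurons x %d frames @ %g Hz (%d excluded)\n",
              nrow(x$dff), ncol(x$dff), x$frame_rate_hz, length(x$excluded)))
  invisible(x)
}

# Exact solution of min ||c - y||^2  s.t.  c[1] >= 0, c[t] >= gam * c[t-1],
# by pool-adjacent-violators on the AR(1) reparameterization. Equivalent to
# nonnegative least squares of y against the causal exponential kernel
# (events e with c = K e, e = c[t] - gam * c[t-1] >= 0).
ar1_pava <- function(y, gam) {
  n <- length(y)
  v <- numeric(n); w <- numeric(n); len <- integer(n)
  m <- 0L
  for (t in seq_len(n)) {
    m <- m + 1L
    v[m] <- y[t]; w[m] <- 1; len[m] <- 1L
    while (m > 1L && v[m] < gam^len[m - 1L] * v[m - 1L]) {
      g <- gam^len[m - 1L]
      v[m - 1L] <- (w[m - 1L] * v[m - 1L] + g * w[m] * v[m]) /
        (w[m - 1L] + g^2 * w[m])
      w[m - 1L] <- w[m - 1L] + g^2 * w[m]
      len[m - 1L] <- len[m - 1L] + len[m]
      m <- m - 1L
    }
  }
  # negative-valued pools can only form a prefix; the e >= 0 constraint at
  # the first frame clamps them to zero
  i <- 1L
  while (i <= m && v[i] < 0) { v[i] <- 0; i <- i + 1L }
  c_fit <- numeric(n)
  pos <- 1L
  for (i in seq_len(m)) {
    idx <- pos + seq_len(len[i]) - 1L
    c_fit[idx] <- v[i] * gam^(seq_len(len[i]) - 1L)
    pos <- pos + len[i]
  }
  e <- c(c_fit[1], c_fit[-1] - gam * c_fit[-n])
  pmax(e, 0)
}

#' Nonnegative deconvolution of dF/F into event amplitudes
#'
#' Estimates nonnegative event amplitudes `e` minimizing
#' `||dff - K e||^2` subject to `e >= 0`, where `K` is the causal
#' single-exponential kernel with per-frame decay
#' `exp(-1 / (tau_s * frame_rate))`. Solved exactly and in linear time per
#' trace by pool-adjacent-violators on the equivalent isotonic formulation.
#'
#' @param dff a `dff_traces` object, or a numeric matrix/vector of dF/F.
#' @param tau_s indicator decay time constant in seconds (> 0).
#' @param frame_rate_hz frame rate; taken from `dff` when it is a
#'   `dff_traces`.
#' @return An `event_traces` object: `events` (neurons x frames, >= 0;
#'   `NA` rows propagate from excluded neurons), `tau_s`, `frame_rate_hz`.
#' @export
deconvolve <- function(dff, tau_s = 0.5, frame_rate_hz = NULL) {
  if (tau_s <= 0) stop("tau_s must be > 0")
  if (inherits(dff, "dff_traces")) {
    frame_rate_hz <- dff$frame_rate_hz
    mat <- dff$dff
  } else {
    if (is.null(frame_rate_hz)) stop("frame_rate_hz required for raw input")
    mat <- if (is.matrix(dff)) dff else matrix(dff, nrow = 1)
  }
  gam <- exp(-1 / (tau_s * frame_rate_hz))
  ev <- matrix(NA_real_, nrow(mat), ncol(mat))
  for (i in seq_len(nrow(mat))) {
    if (all(is.finite(mat[i, ]))) ev[i, ] <- ar1_pava(mat[i, ], gam)
  }
  structure(list(events = ev, tau_s = tau_s, frame_rate_hz = frame_rate_hz),
            class = "event_traces")
}

#' @export
print.event_traces <- function(x, ...) {
  cat(sprintf("<event_traces> %d neurons x %d frames, tau=%g s\n",
              nrow(x$events), ncol(x$events), x$tau_s))
  invisible(x)
}

#' Per-neuron firing rate from deconvolved events
#'
#' Counts frames whose event amplitude exceeds `threshold` within a frame
#' window and divides by the window duration. By default every strictly
#' positive event frame counts; with noisy recordings a small amplitude
#' threshold (e.g. half the single-event dF/F amplitude) suppresses
#' noise-fitted micro-events.
#'
#' @param events an `event_traces` object.
#' @param window integer vector of frame indices (default: all frames).
#' @param threshold amplitude threshold; frames with `events > threshold`
#'   count as event frames.
#' @return per-neuron rate in events/s (`NA` for excluded neurons).
#' @export
firing_rate <- function(events, window = NULL, threshold = 0) {
  stopifnot(inherits(events, "event_traces"))
  window <- window %||% seq_len(ncol(events$events))
  if (length(window) == 0) stop("empty window")
  if (min(window) < 1 || max(window) > ncol(events$events)) {
    stop("window outside trace")
  }
  dur_s <- length(window) / events$frame_rate_hz
  rowSums(events$events[, window, drop = FALSE] > threshold) / dur_s
}
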