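# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 30-neuron control grating session + dF/F, reused across metric tests.
fix_ctl_small <- function() {
  cached("ctl_small", function() {
    s <- simulate_session("gratings", sim_config(30, "control", seed = 5))
    list(session = s, dff = compute_dff(s$recording))
  })
}

# Dense exponential-kernel matrix, the textbook form of the deconvolution
# design; used only by oracles.
exp_kernel_matrix <- function(n, gam) {
  outer(seq_len(n), seq_len(n), function(i, j) ifelse(i >= j, gam^(i - j), 0))
}

# Build a trial_tensor directly from a neuron x condition x trial array,
# bypassing trace alignment, for closed-form metric tests.
tensor_from_array <- function(values, window_s = 2, frame_rate_hz = 16) {
  structure(list(values = values, time_courses = NULL, window_s = window_s,
                 frame_rate_hz = frame_rate_hz, source = "matrix"),
            class = "trial_tensor")
}
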