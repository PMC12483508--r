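#' Write / read a synthetic session as plain-text files
#'
#' Serializes a `synthetic_session` into a directory of portable text files:
#' `F_raw.csv` and `F_neuropil.csv` (neurons x frames), `behavior.csv`,
#' `protocol.csv`, `config.json` and the ground-truth tables under `truth_*`.
#' The round trip restores the recording, protocol, truth and config (the
#' intermediate `rates`/`spikes` matrices are not persisted).
#'
#' @param session a `synthetic_session` from [simulate_session()].
#' @param dir output directory (created if missing).
#' @return `read_session` returns the restored `synthetic_session`.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_mat <- function(m, f) {
    utils::write.table(m, fp(f), sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  write_mat(session$recording$F_raw, "F_raw.csv")
  write_mat(session$recording$F_neuropil, "F_neuropil.csv")
  write.csv(session$recording$behavior, fp("behavior.csv"), row.names = FALSE)
  write_protocol(session$protocol, fp("protocol.csv"))
  tr <- session$truth
  write.csv(data.frame(preferred_direction = tr$preferred_direction,
                       tuning_gain = tr$tuning_gain,
                       w_running = tr$behavior_weights[, 1],
                       w_pupil = tr$behavior_weights[, 2],
                       is_tuned = tr$is_tuned,
                       is_behavior_coupled = tr$is_behavior_coupled),
            fp("truth_neurons.csv"), row.names = FALSE)
  write_mat(tr$latent_loadings, "truth_latent_loadings.csv")
  cfg <- unclass(session$config)
  jsonlite::write_json(cfg, fp("config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  fp <- function(f) file.path(dir, f)
  read_mat <- function(f) {
    as.matrix(utils::read.table(fp(f), sep = ",", header = FALSE))
  }
  cfg <- jsonlite::read_json(fp("config.json"), simplifyVector = TRUE)
  config <- do.call(sim_config, cfg)
  F_raw <- unname(read_mat("F_raw.csv"))
  F_neuropil <- unname(read_mat("F_neuropil.csv"))
  behavior <- read.csv(fp("behavior.csv"))
  protocol <- read_protocol(fp("protocol.csv"))
  tn <- read.csv(fp("truth_neurons.csv"))
  truth <- structure(list(
    preferred_direction = tn$preferred_direction,
    tuning_gain = tn$tuning_gain,
    behavior_weights = cbind(running = tn$w_running, pupil = tn$w_pupil),
    is_tuned = tn$is_tuned,
    is_behavior_coupled = tn$is_behavior_coupled,
    latent_loadings = unname(read_mat("truth_latent_loadings.csv"))),
    class = "ground_truth")
  rec <- pop_recording(F_raw, F_neuropil, config$frame_rate_hz, behavior)
  structure(list(recording = rec, protocol = protocol, truth = truth,
                 config = config, rates = NULL, spikes = NULL),
            class = "synthetic_session")
}
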