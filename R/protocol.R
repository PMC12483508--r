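#' Build a visual stimulation protocol
#'
#' Generates the presentation table for one imaging session of one of the
#' three session types:
#' \describe{
#'   \item{`gray`}{640 s of static gray screen (spontaneous activity); no
#'     labeled presentations.}
#'   \item{`gratings`}{16 trials, each a fixed-order set of 8 drifting-grating
#'     directions (45 deg apart); every grating is shown for 2 s preceded by a
#'     3 s OFF period. 128 presentations, 640 s.}
#'   \item{`movies`}{32 trials, each a 3 s OFF period followed by 7
#'     consecutive 2 s natural-movie clips in fixed order. 224 presentations,
#'     544 s.}
#' }
#'
#' @param kind `"gray"`, `"gratings"` or `"movies"`.
#' @param frame_rate_hz imaging frame rate in Hz (default 16).
#' @return A `stim_protocol`: a data.frame with columns `label` (0-based
#'   condition id), `onset_frame` (1-based), `duration_frames`, carrying
#'   attributes `kind`, `n_trials`, `n_conditions`, `frame_rate_hz`,
#'   `n_frames` (total session length in frames).
#' @examples
#' p <- make_protocol("gratings", 16)
#' nrow(p)                      # 128 presentations
#' attr(p, "n_frames") / 16     # 640 s
#' @export
make_protocol <- function(kind = c("gray", "gratings", "movies"),
                          frame_rate_hz = 16) {
  if (length(kind) == 1L && !kind %in% c("gray", "gratings", "movies")) {
    stop("unknown protocol kind: ", kind)
  }
  kind <- match.arg(kind)
  stopifnot(is.finite(frame_rate_hz), frame_rate_hz > 0)
  sec <- function(s) as.integer(round(s * frame_rate_hz))

  if (kind == "gray") {
    pres <- data.frame(label = integer(0), onset_frame = integer(0),
                       duration_frames = integer(0))
    n_trials <- 0L; n_conditions <- 0L; n_frames <- sec(640)
  } else if (kind == "gratings") {
    n_trials <- 16L; n_conditions <- 8L
    off <- sec(3); on <- sec(2); per <- off + on
    p <- 0:(n_trials * n_conditions - 1L)
    pres <- data.frame(
      label = rep.int(0:(n_conditions - 1L), n_trials),
      onset_frame = p * per + off + 1L,
      duration_frames = on)
    n_frames <- n_trials * n_conditions * per
  } else {
    n_trials <- 32L; n_conditions <- 7L
    off <- sec(3); clip <- sec(2); per_trial <- off + n_conditions * clip
    idx <- expand.grid(clip = 0:(n_conditions - 1L), trial = 0:(n_trials - 1L))
    pres <- data.frame(
      label = idx$clip,
      onset_frame = idx$trial * per_trial + off + idx$clip * clip + 1L,
      duration_frames = clip)
    n_frames <- n_trials * per_trial
  }
  structure(pres,
            kind = kind, n_trials = n_trials, n_conditions = n_conditions,
            frame_rate_hz = frame_rate_hz, n_frames = as.integer(n_frames),
            class = c("stim_protocol", "data.frame"))
}

#' Per-frame condition labels of a protocol
#'
#' @param protocol a `stim_protocol`.
#' @return Integer vector of length `n_frames`; `NA` during OFF/gray frames,
#'   otherwise the 0-based condition label shown at that frame.
#' @export
frame_labels <- function(protocol) {
  n <- attr(protocol, "n_frames")
  lab <- rep.int(NA_integer_, n)
  for (i in seq_len(nrow(protocol))) {
    j <- protocol$onset_frame[i] + seq_len(protocol$duration_frames[i]) - 1L
    lab[j] <- protocol$label[i]
  }
  lab
}

#' Reconstruct a presentation table from per-frame labels
#'
#' Inverse of [frame_labels()] for protocols whose same-label presentations
#' never abut; used as the protocol round-trip check.
#'
#' @param labels integer vector with `NA` for unlabeled frames.
#' @return data.frame with `label`, `onset_frame`, `duration_frames`.
#' @export
presentations_from_labels <- function(labels) {
  r <- rle(ifelse(is.na(labels), -1L, labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values >= 0L
  data.frame(label = r$values[keep],
             onset_frame = starts[keep],
             duration_frames = r$lengths[keep])
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> kind=%s: %d presentations, %d conditions x %d trials, %d frames @ %g Hz\n",
              attr(x, "kind"), nrow(x), attr(x, "n_conditions"),
              attr(x, "n_trials"), attr(x, "n_frames"), attr(x, "frame_rate_hz")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 3))
  invisible(x)
}

#' Write / read a protocol as CSV
#'
#' The CSV holds the presentation table plus a header comment line with the
#' protocol attributes, so the round trip is lossless.
#' @param protocol a `stim_protocol`.
#' @param path file path.
#' @return `read_protocol` returns the `stim_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  meta <- sprintf("#kind=%s,n_trials=%d,n_conditions=%d,frame_rate_hz=%g,n_frames=%d",
                  attr(protocol, "kind"), attr(protocol, "n_trials"),
                  attr(protocol, "n_conditions"), attr(protocol, "frame_rate_hz"),
                  attr(protocol, "n_frames"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(meta, con)
  write.csv(as.data.frame(protocol), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  meta <- sub("^#", "", readLines(path, n = 1L))
  kv <- strsplit(strsplit(meta, ",")[[1]], "=")
  vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  pres <- read.csv(path, comment.char = "#")
  structure(pres,
            kind = vals[["kind"]],
            n_trials = as.integer(vals[["n_trials"]]),
            n_conditions = as.integer(vals[["n_conditions"]]),
            frame_rate_hz = as.numeric(vals[["frame_rate_hz"]]),
            n_frames = as.integer(vals[["n_frames"]]),
            class = c("stim_protocol", "data.frame"))
}
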