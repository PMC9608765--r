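#' Windowing specification
#'
#' Trials are cut into fixed-length overlapping analysis windows after
#' trimming the posture-transition ramps at both trial ends. The window length
#' N is `round(length_ms * fs / 1000)` samples and the hop is
#' `floor(N * (1 - overlap_fraction))` samples (at least 1); a trailing
#' partial window is discarded.
#'
#' @param length_ms Window length in milliseconds.
#' @param overlap_fraction Fractional overlap between consecutive windows,
#'   in \[0, 1).
#' @param trim_s Seconds removed from each end of the trial before windowing,
#'   isolating the steady-state contraction.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_ms = 250, overlap_fraction = 0.5, trim_s = 0.5) {
  if (length_ms <= 0) stop("length_ms must be positive", call. = FALSE)
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)", call. = FALSE)
  if (trim_s < 0) stop("trim_s must be >= 0", call. = FALSE)
  structure(list(length_ms = length_ms, overlap_fraction = overlap_fraction,
                 trim_s = trim_s),
            class = "window_spec")
}

window_length_samples <- function(spec, fs) {
  n <- round(spec$length_ms * fs / 1000)
  if (n < 2) stop("window of ", spec$length_ms, " ms at ", fs,
                  " Hz has fewer than 2 samples", call. = FALSE)
  as.integer(n)
}

#' Segment a recording into analysis windows
#'
#' @param recording A [semg_recording()].
#' @param spec A [window_spec()].
#' @return An object of class `semg_windows` holding the trial samples, the
#'   ordered window start offsets, the window length `n` and hop, and the
#'   recording's metadata (`posture`, `session_id`, `day_id`, `subject_id`,
#'   `channel_names`, `fs`) inherited by every window. Use [window_list()] to
#'   materialise the individual channels x N window matrices.
#' @export
segment_windows <- function(recording, spec = window_spec()) {
  validate_recording(recording)
  n <- window_length_samples(spec, recording$fs)
  trim <- round(spec$trim_s * recording$fs)
  total <- n_samples(recording)
  kept <- total - 2L * trim
  if (kept < n)
    stop("trial too short: ", total, " samples leave ", max(kept, 0),
         " after trimming but at least ", n, " are required", call. = FALSE)
  hop <- max(1L, as.integer(floor(n * (1 - spec$overlap_fraction))))
  starts <- seq.int(trim + 1L, by = hop,
                    length.out = (kept - n) %/% hop + 1L)
  structure(list(samples = recording$samples, starts = as.integer(starts),
                 n = n, hop = hop,
                 posture = recording$posture,
                 session_id = recording$session_id,
                 day_id = recording$day_id,
                 subject_id = recording$subject_id,
                 channel_names = recording$channel_names,
                 fs = recording$fs),
            class = "semg_windows")
}

#' Materialise the windows of a segmented recording
#'
#' @param x A `semg_windows` object from [segment_windows()].
#' @return List of channels x N numeric matrices, one per window, in order.
#' @export
window_list <- function(x) {
  stopifnot(inherits(x, "semg_windows"))
  lapply(x$starts, function(s)
    x$samples[, s:(s + x$n - 1L), drop = FALSE])
}

#' @export
print.semg_windows <- function(x, ...) {
  cat(sprintf("<semg_windows> %d windows of %d samples (hop %d) | '%s'\n",
              length(x$starts), x$n, x$hop, x$posture))
  invisible(x)
}

#' Segment every recording of a dataset
#'
#' Convenience wrapper applying [segment_windows()] to a list of recordings.
#'
#' @param recordings List of [semg_recording()].
#' @param spec A [window_spec()].
#' @return List of `semg_windows`, one element per recording.
#' @export
segment_dataset <- function(recordings, spec = window_spec()) {
  lapply(recordings, segment_windows, spec = spec)
}
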