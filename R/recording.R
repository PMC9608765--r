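#' The twelve-posture vocabulary
#'
#' Ordered, closed vocabulary of the hand postures recognised by the pipeline.
#' The order is fixed and shared by confusion matrices, accuracy tables and
#' radar patterns. A thirteenth pseudo-label, `"rest-calibration"`, marks
#' baseline trials used only for threshold calibration and is not part of the
#' classification vocabulary.
#'
#' @return Character vector of length 12.
#' @export
#' @examples
#' posture_vocabulary()
posture_vocabulary <- function() {
  c("rest", "spread", "finger pointing", "scissor sign", "V sign",
    "O.K. sign", "thumb up (hook)", "cylindrical grasp", "spherical grasp",
    "lateral pinch", "palmar pinch", "tip pinch")
}

REST_CAL_LABEL <- "rest-calibration"

#' Construct a multichannel sEMG recording
#'
#' One trial: a channels x samples numeric matrix at a fixed sampling rate,
#' carrying posture / session / day / subject metadata. Sample values are
#' unitless (amplifier counts); no volt conversion is attempted.
#'
#' @param samples Numeric matrix, channels x time samples.
#' @param fs Sampling rate in Hz (the reference acquisition rate is 1926 Hz).
#' @param posture Label from [posture_vocabulary()] or `"rest-calibration"`.
#' @param session_id Integer session index within a day (1..10 in the
#'   reference protocol).
#' @param day_id Integer training day, >= 1.
#' @param subject_id Subject identifier string.
#' @param channel_names Character vector of muscle labels, one per channel
#'   (e.g. FDS, ED, ECU). Defaults to `ch1..chC`.
#' @return An object of class `semg_recording`.
#' @export
semg_recording <- function(samples, fs, posture,
                           session_id = 1L, day_id = 1L,
                           subject_id = "S1", channel_names = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(samples)))
  }
  rec <- structure(list(
    samples = samples,
    fs = as.numeric(fs),
    posture = as.character(posture),
    session_id = as.integer(session_id),
    day_id = as.integer(day_id),
    subject_id = as.character(subject_id),
    channel_names = as.character(channel_names)
  ), class = "semg_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "semg_recording"))
  if (nrow(rec$samples) < 1L)
    stop("recording must have at least one channel", call. = FALSE)
  if (!is.finite(rec$fs) || rec$fs <= 0)
    stop("sampling rate fs must be a positive number", call. = FALSE)
  if (length(rec$channel_names) != nrow(rec$samples))
    stop("channel_names length (", length(rec$channel_names),
         ") does not match channel count (", nrow(rec$samples), ")",
         call. = FALSE)
  vocab <- c(posture_vocabulary(), REST_CAL_LABEL)
  if (!rec$posture %in% vocab)
    stop("posture label '", rec$posture, "' is outside the closed vocabulary; ",
         "allowed labels: ", paste(vocab, collapse = ", "), call. = FALSE)
  if (rec$session_id < 1L || rec$day_id < 1L)
    stop("session_id and day_id must be >= 1", call. = FALSE)
  invisible(rec)
}

n_channels <- function(rec) nrow(rec$samples)
n_samples <- function(rec) ncol(rec$samples)

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf("<semg_recording> %s | day %d session %d | '%s'\n",
              x$subject_id, x$day_id, x$session_id, x$posture))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.2f s)\n",
              n_channels(x), n_samples(x), x$fs, n_samples(x) / x$fs))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

# rms of a numeric vector
rms <- function(x) sqrt(mean(x^2))
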