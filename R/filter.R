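#' Band-pass filter specification
#'
#' The conditioning stage uses a fourth-order Butterworth band-pass with a
#' 10--500 Hz passband, applied per channel. Filtering is zero-phase
#' (forward-backward) by default because the analysis is offline; set
#' `causal = TRUE` to emulate a real-time single-pass filter.
#'
#' @param low_hz Lower cutoff in Hz.
#' @param high_hz Upper cutoff in Hz.
#' @param order Filter order of the underlying Butterworth design.
#' @param causal Apply a single forward pass instead of forward-backward.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 10, high_hz = 500, order = 4, causal = FALSE) {
  if (!(low_hz > 0 && high_hz > low_hz))
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  if (order < 1) stop("filter order must be >= 1", call. = FALSE)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 causal = isTRUE(causal)),
            class = "filter_spec")
}

butter_design <- function(spec, fs) {
  if (spec$high_hz >= fs / 2)
    stop("high_hz (", spec$high_hz, " Hz) must be below the Nyquist frequency ",
         fs / 2, " Hz", call. = FALSE)
  signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                 type = "pass")
}

#' Band-pass condition a recording
#'
#' Applies the Butterworth band-pass of `spec` to every channel of a
#' recording. The default zero-phase (forward-backward) pass removes the DC
#' component and phase distortion; output has the same shape as the input.
#'
#' @param recording A [semg_recording()].
#' @param spec A [filter_spec()]; defaults to 4th-order 10--500 Hz.
#' @return The filtered recording.
#' @export
#' @examples
#' rec <- semg_recording(matrix(sin(2 * pi * 100 * (0:1925) / 1926), 1), 1926,
#'                       "rest")
#' flt <- bandpass_filter(rec)
bandpass_filter <- function(recording, spec = filter_spec()) {
  validate_recording(recording)
  bf <- butter_design(spec, recording$fs)
  out <- recording
  for (c in seq_len(n_channels(recording))) {
    x <- recording$samples[c, ]
    out$samples[c, ] <- if (spec$causal)
      as.numeric(signal::filter(bf, x))
    else
      as.numeric(signal::filtfilt(bf, x))
  }
  out
}

#' Frequency-response magnitude of the conditioning filter
#'
#' Gain of the designed digital Butterworth band-pass at given frequencies,
#' for the zero-phase (squared-magnitude) or causal (magnitude) variant.
#' Useful for verifying passband flatness and stopband rejection analytically.
#'
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz.
#' @param freqs_hz Frequencies at which to evaluate the gain.
#' @return Numeric vector of linear gains.
#' @export
filter_gain <- function(spec, fs, freqs_hz) {
  bf <- butter_design(spec, fs)
  w <- 2 * pi * freqs_hz / fs
  z <- exp(1i * w)
  h <- vapply(z, function(zz)
    sum(bf$b * zz^(-(seq_along(bf$b) - 1))) /
      sum(bf$a * zz^(-(seq_along(bf$a) - 1))), complex(1))
  g <- Mod(h)
  if (!spec$causal) g <- g^2  # forward-backward pass squares the magnitude
  g
}
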