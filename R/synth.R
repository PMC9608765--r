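#' Default per-posture, per-channel activation profile (healthy 9-channel montage)
#'
#' Mean activation targets (unitless RMS) for the 12 postures over the nine
#' forearm muscles FDS, ED, EDM, EP, FCR, FCU, ECR, ECU, BR. The block
#' structure makes cylindrical vs spherical grasp and palmar vs tip pinch the
#' two hardest pairs: each pair shares most of its activation profile and is
#' separated mainly by small amplitude offsets and by spectral content.
#'
#' @return 12 x 9 numeric matrix with posture row names and muscle column
#'   names.
#' @export
default_amplitude_matrix <- function() {
  chn <- c("FDS", "ED", "EDM", "EP", "FCR", "FCU", "ECR", "ECU", "BR")
  a <- rbind(
    "rest"              = c(.08, .08, .08, .08, .08, .08, .08, .08, .08),
    "spread"            = c(.15, .90, .70, .55, .12, .12, .50, .50, .20),
    "finger pointing"   = c(.40, .80, .30, .20, .20, .15, .30, .25, .15),
    "scissor sign"      = c(.35, .70, .55, .25, .18, .15, .25, .30, .15),
    "V sign"            = c(.30, .75, .60, .30, .15, .12, .35, .30, .15),
    "O.K. sign"         = c(.60, .30, .15, .50, .40, .25, .30, .20, .25),
    "thumb up (hook)"   = c(.25, .35, .20, .80, .20, .20, .40, .30, .30),
    "cylindrical grasp" = c(.80, .30, .15, .15, .50, .50, .25, .30, .40),
    "spherical grasp"   = c(.75, .35, .20, .18, .55, .45, .28, .32, .45),
    "lateral pinch"     = c(.50, .25, .12, .60, .40, .30, .35, .22, .30),
    "palmar pinch"      = c(.60, .25, .12, .45, .35, .28, .30, .20, .28),
    "tip pinch"         = c(.58, .22, .14, .50, .33, .30, .28, .22, .26))
  colnames(a) <- chn
  a
}

#' Default spectral-centroid profile (Hz)
#'
#' Per-posture, per-channel centre frequency of the band-limited noise
#' carrier. Postures differ modestly in spectral content; the two hard
#' amplitude pairs (cylindrical/spherical grasp, palmar/tip pinch) are given
#' distinct centroids so that the frequency-sensitive ZC/SSC features carry
#' genuine extra information over MAV alone.
#'
#' @return 12 x 9 numeric matrix of centre frequencies in Hz.
#' @export
default_centroid_matrix <- function() {
  a <- default_amplitude_matrix()
  base <- c(rest = 110, spread = 150, `finger pointing` = 135,
            `scissor sign` = 160, `V sign` = 125, `O.K. sign` = 145,
            `thumb up (hook)` = 115, `cylindrical grasp` = 120,
            `spherical grasp` = 145, `lateral pinch` = 130,
            `palmar pinch` = 120, `tip pinch` = 150)
  m <- matrix(rep(base[rownames(a)], ncol(a)), nrow(a), ncol(a),
              dimnames = dimnames(a))
  # mild channel gradient so channels are not spectrally identical
  sweep(m, 2L, seq(-10, 10, length.out = ncol(a)), `+`)
}

#' Synthetic sEMG study configuration
#'
#' Full parameterisation of the generator. Defaults reproduce the reference
#' protocol: 12 postures x 10 sessions/day at 1926 Hz, 5 s trials, nine
#' channels, a three-day amplitude-dispersion schedule (0.5, 0.25, 0.1)
#' emulating the variability reduction induced by visual-feedback training,
#' and mild inter-channel crosstalk.
#'
#' @param n_channels Number of sEMG channels.
#' @param postures Subset of [posture_vocabulary()].
#' @param amplitude_matrix postures x channels nonnegative mean-activation
#'   targets (unitless RMS).
#' @param spectral_centroid_matrix postures x channels carrier centre
#'   frequencies in Hz; carriers are 4th-order band-passes with relative
#'   bandwidth 0.6 around the centroid.
#' @param sigma_trial Per-day multiplicative log-normal amplitude dispersion
#'   schedule; length = number of simulated days.
#' @param crosstalk_lambda Off-diagonal leakage fraction, in \[0, 0.5).
#' @param rest_amplitude Baseline RMS of the rest-calibration trials.
#' @param fs Sampling rate in Hz.
#' @param trial_s Trial duration in seconds.
#' @param sessions_per_day Sessions recorded per day.
#' @param seed Integer RNG seed; the full dataset is a deterministic function
#'   of the configuration.
#' @param channel_names Channel (muscle) labels.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_channels = 9L,
                         postures = posture_vocabulary(),
                         amplitude_matrix = NULL,
                         spectral_centroid_matrix = NULL,
                         sigma_trial = c(0.5, 0.25, 0.1),
                         crosstalk_lambda = 0.05,
                         rest_amplitude = 0.05,
                         fs = 1926,
                         trial_s = 5,
                         sessions_per_day = 10L,
                         seed = 1L,
                         channel_names = NULL) {
  if (!length(postures)) stop("posture set must be nonempty", call. = FALSE)
  bad <- setdiff(postures, posture_vocabulary())
  if (length(bad))
    stop("unknown postures: ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(amplitude_matrix)) {
    amplitude_matrix <- default_amplitude_matrix()[postures, seq_len(n_channels),
                                                   drop = FALSE]
  }
  if (is.null(spectral_centroid_matrix)) {
    spectral_centroid_matrix <-
      default_centroid_matrix()[postures, seq_len(n_channels), drop = FALSE]
  }
  if (is.null(channel_names)) {
    channel_names <- colnames(amplitude_matrix)
    if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n_channels))
  }
  amplitude_matrix <- as.matrix(amplitude_matrix)
  spectral_centroid_matrix <- as.matrix(spectral_centroid_matrix)
  if (any(amplitude_matrix < 0))
    stop("amplitude_matrix must be nonnegative", call. = FALSE)
  if (!all(dim(amplitude_matrix) == c(length(postures), n_channels)))
    stop("amplitude_matrix must be ", length(postures), " x ", n_channels,
         call. = FALSE)
  if (!all(dim(spectral_centroid_matrix) == dim(amplitude_matrix)))
    stop("spectral_centroid_matrix shape must match amplitude_matrix",
         call. = FALSE)
  if (any(spectral_centroid_matrix <= 0 |
          spectral_centroid_matrix * 1.3 >= fs / 2))
    stop("spectral centroids must lie in (0, fs/2/1.3) so the carrier band ",
         "stays below Nyquist", call. = FALSE)
  if (any(sigma_trial < 0)) stop("sigma_trial must be >= 0", call. = FALSE)
  if (crosstalk_lambda < 0 || crosstalk_lambda >= 0.5)
    stop("crosstalk_lambda must be in [0, 0.5)", call. = FALSE)
  if (trial_s <= 0 || fs <= 0 || sessions_per_day < 1L)
    stop("invalid fs / trial_s / sessions_per_day", call. = FALSE)
  rownames(amplitude_matrix) <- postures
  rownames(spectral_centroid_matrix) <- postures
  structure(list(
    n_channels = as.integer(n_channels), postures = postures,
    amplitude_matrix = amplitude_matrix,
    spectral_centroid_matrix = spectral_centroid_matrix,
    sigma_trial = sigma_trial, crosstalk_lambda = crosstalk_lambda,
    rest_amplitude = rest_amplitude, fs = fs, trial_s = trial_s,
    sessions_per_day = as.integer(sessions_per_day), seed = as.integer(seed),
    channel_names = channel_names), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("<synth_config> %d postures x %d channels | %d day(s) x ",
                     "%d sessions | %g s @ %g Hz\n"),
              length(x$postures), x$n_channels, length(x$sigma_trial),
              x$sessions_per_day, x$trial_s, x$fs))
  cat(sprintf("  sigma schedule: %s | crosstalk lambda: %g | seed: %d\n",
              paste(x$sigma_trial, collapse = ", "), x$crosstalk_lambda,
              x$seed))
  invisible(x)
}

# unit-RMS band-limited Gaussian carrier around a centre frequency,
# relative bandwidth 0.6 (band [0.7 fc, 1.3 fc]), 4th-order Butterworth;
# single-pass filter (carrier phase is irrelevant), start-up transient dropped
bandlimited_noise <- function(n, fc, fs) {
  bf <- signal::butter(4, c(0.7 * fc, 1.3 * fc) / (fs / 2), type = "pass")
  pad <- 200L
  x <- as.numeric(signal::filter(bf, stats::rnorm(n + pad)))[-seq_len(pad)]
  x / rms(x)
}

#' Mix channels with a symmetric row-stochastic crosstalk matrix
#'
#' Models electrode crosstalk as linear leakage: the mixing matrix has
#' `1 - lambda` on the diagonal and `lambda / (C - 1)` off-diagonal, so each
#' row sums to one and a channel-constant signal passes unchanged.
#'
#' @param trial_matrix channels x samples numeric matrix.
#' @param lambda Leakage fraction in \[0, 0.5).
#' @return Mixed matrix of the same shape.
#' @export
apply_crosstalk <- function(trial_matrix, lambda) {
  if (lambda < 0 || lambda >= 0.5)
    stop("lambda must be in [0, 0.5)", call. = FALSE)
  C <- nrow(trial_matrix)
  if (lambda == 0 || C == 1L) return(trial_matrix)
  M <- matrix(lambda / (C - 1), C, C)
  diag(M) <- 1 - lambda
  M %*% trial_matrix
}

#' Generate a synthetic multi-day sEMG dataset
#'
#' For each simulated day and session the generator emits one 5 s trial per
#' posture in a seeded random order, plus one rest-calibration trial.
#' Channel c of posture p is band-limited Gaussian noise with realised RMS
#' `amplitude_matrix[p, c] * exp(eps)`, `eps ~ N(0, sigma_trial[day]^2)` drawn
#' independently per channel and trial, spectrally centred per
#' `spectral_centroid_matrix`, then mixed across channels by the crosstalk
#' matrix. The whole dataset is a deterministic function of the config
#' (including its seed).
#'
#' @param config A [synth_config()].
#' @return List with `recordings` (list of [semg_recording()]) and
#'   `ground_truth` (data.frame: trial index, day, session, posture, and the
#'   realised per-channel amplitude matrix in column `amplitude`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  P <- length(config$postures)
  C <- config$n_channels
  n <- round(config$trial_s * config$fs)
  recs <- list(); gt_day <- integer(); gt_sess <- integer()
  gt_post <- character(); gt_amp <- list()
  for (day in seq_along(config$sigma_trial)) {
    sigma <- config$sigma_trial[day]
    for (sess in seq_len(config$sessions_per_day)) {
      ord <- sample.int(P)
      for (p in ord) {
        eps <- stats::rnorm(C, 0, sigma)
        amp <- config$amplitude_matrix[p, ] * exp(eps)
        x <- matrix(0, C, n)
        for (c in seq_len(C)) {
          if (amp[c] > 0)
            x[c, ] <- amp[c] *
              bandlimited_noise(n, config$spectral_centroid_matrix[p, c],
                                config$fs)
        }
        x <- apply_crosstalk(x, config$crosstalk_lambda)
        recs[[length(recs) + 1L]] <- semg_recording(
          x, config$fs, config$postures[p], session_id = sess, day_id = day,
          subject_id = "synthetic", channel_names = config$channel_names)
        gt_day <- c(gt_day, day); gt_sess <- c(gt_sess, sess)
        gt_post <- c(gt_post, config$postures[p])
        gt_amp[[length(gt_amp) + 1L]] <- unname(amp)
      }
      # rest-calibration trial closing the session
      xr <- matrix(0, C, n)
      if (config$rest_amplitude > 0) {
        for (c in seq_len(C))
          xr[c, ] <- config$rest_amplitude * bandlimited_noise(n, 120, config$fs)
      }
      recs[[length(recs) + 1L]] <- semg_recording(
        xr, config$fs, REST_CAL_LABEL, session_id = sess, day_id = day,
        subject_id = "synthetic", channel_names = config$channel_names)
      gt_day <- c(gt_day, day); gt_sess <- c(gt_sess, sess)
      gt_post <- c(gt_post, REST_CAL_LABEL)
      gt_amp[[length(gt_amp) + 1L]] <- rep(config$rest_amplitude, C)
    }
  }
  gt <- data.frame(trial = seq_along(recs), day = gt_day, session = gt_sess,
                   posture = gt_post, stringsAsFactors = FALSE)
  gt$amplitude <- do.call(rbind, gt_amp)
  list(recordings = recs, ground_truth = gt)
}

#' Derive an amputee-montage configuration by removing channels
#'
#' Emulates muscle loss: the listed channels are removed from the montage and
#' the amplitude matrix is rescaled so its global maximum activation is
#' preserved. Postures whose discriminative signal lived only on the lost
#' channels become statistically confusable downstream.
#'
#' @param config A [synth_config()].
#' @param lost_channels Integer indices or channel names to remove (may be
#'   empty, returning the config unchanged).
#' @return A new `synth_config` over the surviving channels.
#' @export
amputee_mode <- function(config, lost_channels) {
  stopifnot(inherits(config, "synth_config"))
  if (is.character(lost_channels))
    lost_channels <- match(lost_channels, config$channel_names)
  lost_channels <- as.integer(lost_channels)
  if (anyNA(lost_channels) || any(lost_channels < 1L |
                                  lost_channels > config$n_channels))
    stop("lost_channels must name existing channels", call. = FALSE)
  keep <- setdiff(seq_len(config$n_channels), lost_channels)
  if (!length(keep))
    stop("cannot remove all channels", call. = FALSE)
  amp <- config$amplitude_matrix[, keep, drop = FALSE]
  if (max(amp) > 0)
    amp <- amp * max(config$amplitude_matrix) / max(amp)
  synth_config(
    n_channels = length(keep), postures = config$postures,
    amplitude_matrix = amp,
    spectral_centroid_matrix =
      config$spectral_centroid_matrix[, keep, drop = FALSE],
    sigma_trial = config$sigma_trial,
    crosstalk_lambda = config$crosstalk_lambda,
    rest_amplitude = config$rest_amplitude, fs = config$fs,
    trial_s = config$trial_s, sessions_per_day = config$sessions_per_day,
    seed = config$seed, channel_names = config$channel_names[keep])
}

#' Read / write a synthetic study configuration as JSON
#'
#' @param path JSON file path.
#' @param config A [synth_config()] (for writing).
#' @return `read_synth_config` returns a `synth_config`;
#'   `write_synth_config` returns `path` invisibly.
#' @export
read_synth_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  synth_config(
    n_channels = j$n_channels, postures = j$postures,
    amplitude_matrix = matrix(j$amplitude_matrix, length(j$postures),
                              j$n_channels,
                              dimnames = list(j$postures, j$channel_names)),
    spectral_centroid_matrix = matrix(j$spectral_centroid_matrix,
                                      length(j$postures), j$n_channels),
    sigma_trial = j$sigma_trial, crosstalk_lambda = j$crosstalk_lambda,
    rest_amplitude = j$rest_amplitude, fs = j$fs, trial_s = j$trial_s,
    sessions_per_day = j$sessions_per_day, seed = j$seed,
    channel_names = j$channel_names)
}

#' @rdname read_synth_config
#' @export
write_synth_config <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  j <- list(n_channels = config$n_channels, postures = config$postures,
            amplitude_matrix = as.numeric(config$amplitude_matrix),
            spectral_centroid_matrix =
              as.numeric(config$spectral_centroid_matrix),
            sigma_trial = config$sigma_trial,
            crosstalk_lambda = config$crosstalk_lambda,
            rest_amplitude = config$rest_amplitude, fs = config$fs,
            trial_s = config$trial_s,
            sessions_per_day = config$sessions_per_day, seed = config$seed,
            channel_names = config$channel_names)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' The shipped healthy-adult nine-channel study fixture
#'
#' Convenience constructor for the default simulated study: 12 postures, nine
#' channels, three days with dispersion schedule (0.5, 0.25, 0.1), ten
#' sessions per day.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [synth_config()].
#' @return A `synth_config`.
#' @export
healthy_fixture_config <- function(seed = 1L, ...) {
  synth_config(seed = seed, ...)
}

#' The shipped amputee eight-channel study fixture
#'
#' An illustrative synthetic scenario of a forearm-amputee montage (BR, FCR,
#' ECR, ED, ECU, FDP, FDS, FCU): derived from the healthy profile over the
#' shared muscles plus a deep finger flexor channel, with the (scissor sign,
#' tip pinch) and (cylindrical grasp, lateral pinch) activation rows pulled
#' toward each other so those pairs are the hardest to separate, and a
#' five-day dispersion schedule. It is a constructed scenario for exercising
#' the pipeline under muscle loss, not a reconstruction of any individual's
#' signal statistics.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [synth_config()].
#' @return A `synth_config`.
#' @export
amputee_fixture_config <- function(seed = 1L, ...) {
  chn <- c("BR", "FCR", "ECR", "ED", "ECU", "FDP", "FDS", "FCU")
  ha <- default_amplitude_matrix()
  hc <- default_centroid_matrix()
  shared <- intersect(chn, colnames(ha))
  amp <- cbind(ha[, shared], FDP = 0.8 * ha[, "FDS"] + 0.08)[, chn]
  cen <- cbind(hc[, shared], FDP = hc[, "FDS"] - 5)[, chn]
  blend <- function(m, a, b, w = 0.75) {
    mid <- (m[a, ] + m[b, ]) / 2
    m[a, ] <- (1 - w) * m[a, ] + w * mid
    m[b, ] <- (1 - w) * m[b, ] + w * mid
    m
  }
  amp <- blend(amp, "scissor sign", "tip pinch")
  amp <- blend(amp, "cylindrical grasp", "lateral pinch")
  cen <- blend(cen, "scissor sign", "tip pinch")
  cen <- blend(cen, "cylindrical grasp", "lateral pinch")
  synth_config(n_channels = 8L, amplitude_matrix = amp,
               spectral_centroid_matrix = cen,
               sigma_trial = c(0.6, 0.45, 0.3, 0.2, 0.12),
               seed = seed, channel_names = chn, ...)
}
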