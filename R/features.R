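#' Time-domain feature primitives
#'
#' The four Hudgins time-domain features computed on a single-channel window
#' of N samples:
#' \itemize{
#'   \item `mav(x)` — mean absolute value, `sum(|x_i|) / N`.
#'   \item `wl(x)` — waveform length, `sum(|x_{i+1} - x_i|)`.
#'   \item `zc(x, threshold)` — zero crossings: adjacent pairs with opposite
#'     sign (`x_i * x_{i+1} < 0`) whose jump clears the noise gate
#'     (`|x_i - x_{i+1}| >= threshold`).
#'   \item `ssc(x, threshold)` — slope sign changes: interior samples where
#'     `(x_i - x_{i-1}) * (x_i - x_{i+1}) >= threshold`.
#' }
#' MAV and WL carry amplitude information; ZC and SSC are time-domain
#' surrogates for spectral content. The threshold is calibrated from the
#' resting baseline via [calibrate_threshold()].
#'
#' @param x Numeric vector (one channel of one window).
#' @param threshold Nonnegative noise-rejection threshold.
#' @return A single nonnegative number; ZC and SSC are integer counts.
#' @name td_features
NULL

#' @rdname td_features
#' @export
mav <- function(x) {
  if (!length(x)) stop("mav: empty window", call. = FALSE)
  mean(abs(x))
}

#' @rdname td_features
#' @export
wl <- function(x) {
  if (length(x) < 2L) stop("wl: window must have >= 2 samples", call. = FALSE)
  sum(abs(diff(x)))
}

#' @rdname td_features
#' @export
zc <- function(x, threshold = 0) {
  if (length(x) < 2L) stop("zc: window must have >= 2 samples", call. = FALSE)
  if (threshold < 0) stop("zc: threshold must be >= 0", call. = FALSE)
  a <- x[-length(x)]
  b <- x[-1L]
  sum(a * b < 0 & abs(a - b) >= threshold)
}

#' @rdname td_features
#' @export
ssc <- function(x, threshold = 0) {
  if (length(x) < 3L) stop("ssc: window must have >= 3 samples", call. = FALSE)
  if (threshold < 0) stop("ssc: threshold must be >= 0", call. = FALSE)
  i <- 2:(length(x) - 1L)
  sum((x[i] - x[i - 1L]) * (x[i] - x[i + 1L]) >= threshold)
}

#' The threshold multiplier grid
#'
#' Candidate values of the threshold multiplier R swept during calibration:
#' 0.0 to 10.0 in steps of 0.5 (21 values).
#'
#' @return Numeric vector of length 21.
#' @export
r_grid <- function() seq(0, 10, by = 0.5)

#' Calibrate per-channel noise thresholds from resting baseline
#'
#' The ZC/SSC noise gate is `R` times the root-mean-square of the resting
#' sEMG, computed per channel. Several rest trials may be supplied; their
#' samples are pooled channel-wise.
#'
#' @param rest_recordings A rest-calibration [semg_recording()] or a list of
#'   them.
#' @param R Nonnegative threshold multiplier (conventionally on [r_grid()]).
#' @return Numeric vector of per-channel thresholds.
#' @export
calibrate_threshold <- function(rest_recordings, R) {
  if (inherits(rest_recordings, "semg_recording"))
    rest_recordings <- list(rest_recordings)
  if (!length(rest_recordings))
    stop("no calibration trial: a rest-calibration recording is required",
         call. = FALSE)
  if (R < 0) stop("R must be >= 0", call. = FALSE)
  pooled <- do.call(cbind, lapply(rest_recordings, function(r) {
    validate_recording(r)
    r$samples
  }))
  R * apply(pooled, 1L, rms)
}

#' Feature extraction configuration
#'
#' @param feature_set `"hudgins"` (MAV, WL, ZC, SSC per channel) or `"mav"`
#'   (MAV only).
#' @param R Threshold multiplier used for bookkeeping; thresholds themselves
#'   are passed explicitly.
#' @param thresholds Per-channel threshold vector from
#'   [calibrate_threshold()]; required for the Hudgins set, ignored for MAV
#'   only.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(feature_set = c("hudgins", "mav"), R = 0,
                           thresholds = NULL) {
  feature_set <- match.arg(feature_set)
  if (!R %in% r_grid())
    message("note: R = ", R, " is off the standard 0.0:0.5:10.0 grid")
  structure(list(feature_set = feature_set, R = R, thresholds = thresholds),
            class = "feature_config")
}

FEATURE_ORDER <- c("MAV", "WL", "ZC", "SSC")

#' Extract a feature matrix from segmented windows
#'
#' Turns one or more `semg_windows` objects into a windows x features matrix.
#' Columns are grouped per channel in the fixed order MAV, WL, ZC, SSC
#' (Hudgins set) or a single MAV column per channel (MAV only); posture
#' labels and session/day identifiers are carried through row-aligned.
#'
#' @param windows A `semg_windows` object from [segment_windows()], or a list
#'   of them (e.g. from [segment_dataset()]).
#' @param config A [feature_config()].
#' @return An object of class `semg_features`: list with `x` (numeric
#'   matrix), `posture`, `session_id`, `day_id` (row-aligned vectors),
#'   `channel_names`, `feature_set` and `R`.
#' @export
extract_features <- function(windows, config = feature_config("hudgins")) {
  if (inherits(windows, "semg_windows")) windows <- list(windows)
  if (!length(windows) || !sum(lengths(lapply(windows, `[[`, "starts"))))
    stop("no windows to extract features from", call. = FALSE)
  chn <- windows[[1L]]$channel_names
  C <- length(chn)
  hudgins <- config$feature_set == "hudgins"
  if (hudgins) {
    thr <- config$thresholds
    if (is.null(thr))
      stop("Hudgins feature set requires calibrated thresholds; ",
           "see calibrate_threshold()", call. = FALSE)
    if (length(thr) != C)
      stop("threshold vector length (", length(thr),
           ") does not match channel count (", C, ")", call. = FALSE)
  }
  nw_per <- vapply(windows, function(w) length(w$starts), integer(1))
  labs <- character(); sess <- integer(); day <- integer()
  x <- matrix(0, sum(nw_per), if (hudgins) 4L * C else C)
  # prefix-sum formulation over each channel's full signal: the per-window
  # sums fall out as differences of cumulative sums, in O(samples) per
  # channel. Equals the scalar primitives applied window by window
  # (asserted against them in the test suite).
  row0 <- 0L
  for (wset in windows) {
    if (!identical(wset$channel_names, chn))
      stop("windows have heterogeneous channel sets", call. = FALSE)
    s <- wset$starts
    N <- wset$n
    rows <- row0 + seq_along(s)
    for (c in seq_len(C)) {
      v <- wset$samples[c, ]
      P <- c(0, cumsum(abs(v)))
      if (hudgins) {
        dv <- diff(v)
        D <- c(0, cumsum(abs(dv)))
        a <- v[-length(v)]; b <- v[-1L]
        Z <- c(0, cumsum(a * b < 0 & abs(a - b) >= thr[c]))
        i <- 2:(length(v) - 1L)
        U <- c(0, cumsum((v[i] - v[i - 1L]) * (v[i] - v[i + 1L]) >= thr[c]))
        x[rows, (c - 1L) * 4L + 1:4] <- cbind(
          (P[s + N] - P[s]) / N,         # MAV: sum |v| over s..s+N-1
          D[s + N - 1L] - D[s],          # WL: diffs s..s+N-2
          Z[s + N - 1L] - Z[s],          # ZC: pairs s..s+N-2
          U[s + N - 2L] - U[s])          # SSC: interior i = s+1..s+N-2
      } else {
        x[rows, c] <- (P[s + N] - P[s]) / N
      }
    }
    labs <- c(labs, rep(wset$posture, length(s)))
    sess <- c(sess, rep(wset$session_id, length(s)))
    day <- c(day, rep(wset$day_id, length(s)))
    row0 <- row0 + length(s)
  }
  colnames(x) <- if (hudgins)
    paste(rep(chn, each = 4L), FEATURE_ORDER, sep = ".")
  else
    paste(chn, "MAV", sep = ".")
  structure(list(x = x, posture = labs, session_id = sess, day_id = day,
                 channel_names = chn, feature_set = config$feature_set,
                 R = config$R),
            class = "semg_features")
}

#' @export
print.semg_features <- function(x, ...) {
  cat(sprintf("<semg_features> %d windows x %d features (%s set, R = %g)\n",
              nrow(x$x), ncol(x$x), x$feature_set, x$R))
  cat("  postures:", paste(unique(x$posture), collapse = ", "), "\n")
  invisible(x)
}

# row-bind two aligned feature objects (internal)
rbind_features <- function(a, b) {
  stopifnot(identical(colnames(a$x), colnames(b$x)))
  structure(list(x = rbind(a$x, b$x),
                 posture = c(a$posture, b$posture),
                 session_id = c(a$session_id, b$session_id),
                 day_id = c(a$day_id, b$day_id),
                 channel_names = a$channel_names,
                 feature_set = a$feature_set, R = a$R),
            class = "semg_features")
}

subset_features <- function(f, idx) {
  structure(list(x = f$x[idx, , drop = FALSE],
                 posture = f$posture[idx],
                 session_id = f$session_id[idx],
                 day_id = f$day_id[idx],
                 channel_names = f$channel_names,
                 feature_set = f$feature_set, R = f$R),
            class = "semg_features")
}

#' Select the threshold multiplier R by held-out-session validation
#'
#' Sweeps the threshold multiplier grid, training the Hudgins-set classifier
#' on all-but-one training session and scoring it on the held-out session,
#' rotating the held-out session. Returns the grid value maximising mean
#' validation accuracy; ties break toward the smaller R (more permissive
#' gating is preferred only when it pays).
#'
#' @param recordings Training recordings spanning at least 2 sessions,
#'   including one rest-calibration trial per session.
#' @param grid Candidate R values, default [r_grid()].
#' @param classifier_spec A [classifier_spec()].
#' @param window_spec A [window_spec()].
#' @param n_rotations Number of held-out-session rotations to average over.
#' @param seed Integer seed controlling classifier initialisation.
#' @return List with `best_R` and `sweep` (data.frame of R vs mean validation
#'   accuracy, for audit).
#' @export
optimize_R <- function(recordings, grid = r_grid(),
                       classifier_spec = NULL,
                       window_spec = semgkit::window_spec(),
                       n_rotations = 2L, seed = 1L) {
  if (is.null(classifier_spec)) classifier_spec <- semgkit::classifier_spec()
  sessions <- sort(unique(vapply(recordings, `[[`, integer(1), "session_id")))
  if (length(sessions) < 2L)
    stop("optimize_R needs >= 2 training sessions (one is held out for ",
         "validation); with a single session pass a fixed R instead",
         call. = FALSE)
  n_rotations <- min(n_rotations, length(sessions))
  held <- sessions[seq_len(n_rotations)]
  wins <- segment_dataset(
    Filter(function(r) r$posture != REST_CAL_LABEL, recordings), window_spec)
  rests <- Filter(function(r) r$posture == REST_CAL_LABEL, recordings)
  if (!length(rests))
    stop("no calibration trial among the training recordings", call. = FALSE)
  sess_of <- function(xs) vapply(xs, `[[`, integer(1), "session_id")
  acc <- matrix(NA_real_, length(grid), length(held))
  for (h in seq_along(held)) {
    tr_w <- wins[sess_of(wins) != held[h]]
    va_w <- wins[sess_of(wins) == held[h]]
    tr_rest <- rests[sess_of(rests) != held[h]]
    for (g in seq_along(grid)) {
      thr <- calibrate_threshold(tr_rest, grid[g])
      cfg <- feature_config("hudgins", R = grid[g], thresholds = thr)
      ftr <- extract_features(tr_w, cfg)
      fva <- extract_features(va_w, cfg)
      mdl <- train_classifier(ftr, classifier_spec, seed = seed)
      acc[g, h] <- mean(predict(mdl, fva) == fva$posture) * 100
    }
  }
  mean_acc <- rowMeans(acc)
  best <- grid[which.max(mean_acc)]  # which.max takes the first, i.e. smallest R
  list(best_R = best,
       sweep = data.frame(R = grid, accuracy = mean_acc))
}
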