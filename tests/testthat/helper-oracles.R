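# Independent brute-force oracles. These are deliberately written as plain
# loops over the defining formulas, sharing no code with the package
# implementation they check.

oracle_mav <- function(x) {
  s <- 0
  for (v in x) s <- s + abs(v)
  s / length(x)
}

oracle_wl <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1L)) s <- s + abs(x[i + 1L] - x[i])
  s
}

oracle_zc <- function(x, thr) {
  n <- 0L
  for (i in seq_len(length(x) - 1L)) {
    if (x[i] * x[i + 1L] < 0 && abs(x[i] - x[i + 1L]) >= thr) n <- n + 1L
  }
  n
}

oracle_ssc <- function(x, thr) {
  n <- 0L
  for (i in 2:(length(x) - 1L)) {
    if ((x[i] - x[i - 1L]) * (x[i] - x[i + 1L]) >= thr) n <- n + 1L
  }
  n
}

rms <- function(x) sqrt(mean(x^2))

# naive pairwise distance matrix from a scalar distance function
oracle_distance_matrix <- function(points, dfun) {
  n <- nrow(points)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) D[i, j] <- dfun(points[i, ], points[j, ])
  }
  D
}

# naive per-point silhouettes from a distance matrix and labels
oracle_silhouette <- function(D, labels) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(D[i, labels == cl]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# brute-force count of full windows: enumerate candidate start indices
oracle_window_count <- function(total, trim, n, hop) {
  cnt <- 0L
  start <- trim + 1L
  while (start + n - 1L <= total - trim) {
    cnt <- cnt + 1L
    start <- start + hop
  }
  cnt
}

# small multichannel recording filled with white noise
make_noise_recording <- function(channels = 2, samples = 600, fs = 500,
                                 posture = "spread", session = 1L, day = 1L,
                                 sd = 1) {
  semg_recording(matrix(rnorm(channels * samples, sd = sd), channels), fs,
                 posture, session_id = session, day_id = day)
}

# compact simulated study used by unit tests (not the shipped fixture scale)
tiny_config <- function(seed = 7L, postures = c("rest", "spread",
                                                "cylindrical grasp",
                                                "tip pinch"),
                        n_channels = 3L, sigma_trial = 0.2,
                        sessions_per_day = 4L, fs = 600, trial_s = 1.2,
                        ...) {
  synth_config(n_channels = n_channels, postures = postures,
               sigma_trial = sigma_trial, sessions_per_day = sessions_per_day,
               fs = fs, trial_s = trial_s, seed = seed, ...)
}

tiny_window_spec <- function() window_spec(length_ms = 250,
                                           overlap_fraction = 0.5,
                                           trim_s = 0.1)

fast_classifier <- function(hidden = 8L) {
  classifier_spec(hidden_layers = hidden, max_epochs = 100L,
                  chunk_epochs = 50L)
}

split_rest <- function(recordings) {
  list(posture = Filter(function(r) r$posture != "rest-calibration",
                        recordings),
       rest = Filter(function(r) r$posture == "rest-calibration", recordings))
}
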