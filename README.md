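# semgkit

Surface electromyography (sEMG) hand-posture recognition, simulation and
variability analysis in R.

## The problem

Myoelectric control — driving a prosthetic hand or a computer interface from
skin-surface recordings of forearm muscle activity — rests on a classic
pattern-recognition pipeline: condition the multichannel sEMG, cut it into
short analysis windows, extract time-domain features, and classify each
window into one of a closed set of hand postures. Performance hinges not
only on the classifier but on how *consistent* the user's muscle-activation
patterns are from trial to trial; biofeedback training that shows the user
their own activation pattern (as a radar plot, one axis per muscle) can
shrink that variability and lift recognition accuracy substantially,
especially for amputees whose residual-limb signals are highly variable.

`semgkit` implements this whole loop for researchers in rehabilitation
engineering and neural interfacing:

- **Conditioning** — per-channel zero-phase 4th-order Butterworth band-pass
  (10–500 Hz default) and overlapping-window segmentation
  (250 ms / 50% default) of trials recorded at 1926 Hz.
- **Features** — the Hudgins time-domain set per channel and window:

  - mean absolute value `MAV = (1/N) Σ |x_i|`
  - waveform length `WL = Σ |x_{i+1} − x_i|`
  - zero crossings `ZC = #{ i : x_i·x_{i+1} < 0 ∧ |x_i − x_{i+1}| ≥ T }`
  - slope sign changes `SSC = #{ i : (x_i − x_{i−1})(x_i − x_{i+1}) ≥ T }`

  with the noise gate `T = R × RMS(rest-trial sEMG)` calibrated per channel
  from a resting baseline, `R` swept over the grid 0.0, 0.5, …, 10.0.
- **Classification** — a single-hidden-layer perceptron (via `nnet`) with
  per-fold z-scoring and early stopping, evaluated by *session-wise ten-fold
  cross-testing*: at training level TRNk, fold f trains on k contiguous
  sessions (of 10 recorded per day) and tests on the remaining 10−k, with
  threshold calibration and normalisation computed inside each fold.
  Results come back as mean ± SD fold accuracy and a row-normalised 12×12
  confusion matrix.
- **Variability analysis** — per-point silhouettes of the per-window MAV
  cloud under the Mahalanobis distance (pooled shrinkage covariance):
  `a_i` = mean within-cluster distance, `b_i` = smallest mean distance to
  another cluster, `s_i = (b_i − a_i)/max(a_i, b_i)` (0 for singletons), and
  the silhouette coefficient `SC = max_J š_J`, the maximum per-cluster mean.
  A t-SNE 2-D embedding (via `Rtsne`) supports visual inspection.
- **Feedback** — per-posture radar target patterns (max-normalised mean MAV
  per channel), a cosine pattern-match score, and radar-plot export.
- **Simulation** — a seeded generator of realistic multichannel datasets:
  per-posture, per-channel amplitude and spectral-centroid profiles drive
  band-limited Gaussian carriers, log-normal trial-to-trial amplitude
  dispersion follows a per-day schedule (emulating training-induced
  variability reduction), and channels are mixed by a row-stochastic
  crosstalk matrix. Every downstream stage is therefore testable with no
  human recordings.

## Worked example

```r
library(semgkit)

# one simulated training day: 12 postures x 10 sessions, moderate variability
cfg <- healthy_fixture_config(seed = 11)
cfg$sigma_trial <- 0.25
sim  <- generate_dataset(cfg)
recs <- lapply(sim$recordings, bandpass_filter)

# session-wise cross-testing at TRN9 with Hudgins' set, R = 2
ev <- cross_test(recs, k = 9, feature_set = "hudgins", R = 2, seed = 1)
print(ev)
#> <semg_eval> day 1 TRN9 (hudgins, R = 2, window vote)
#>   accuracy: 88.9% +/- 5.4% over 10 folds

# cluster quality of the MAV point cloud
f  <- extract_features(segment_dataset(
        Filter(function(r) r$posture != "rest-calibration", recs)),
        feature_config("mav"))
ps <- mav_point_set(f)
print(silhouette_coefficient(ps$points, ps$labels))
#> <silhouette_report> SC = 0.8024 (max of 12 cluster means; mahalanobis)
#>   all-point mean silhouette: 0.1095
```

The evaluation says the classifier recognised ~89% of 250 ms test windows
from the held-out session, averaged over the ten session rotations; the
silhouette report says the best-separated posture cluster has a mean
silhouette of 0.80 (its windows sit far closer to their own posture's
activation pattern than to any other), while the much lower all-point mean
of 0.11 reflects the deliberately hard, overlapping grasp and pinch
clusters.

A full multi-day experiment — both feature sets, every TRN level, per-day
silhouettes and radar targets, written to a results directory with a
manifest that reproduces it bit for bit — is one call:

```r
report <- run_pipeline(pipeline_config(), out_dir = "results/")
```

A thin command-line front end over the same functions ships in
`inst/exec/semgkit` (subcommands `simulate`, `filter`, `features`,
`crosstest`, `cluster`, `embed`, `radar`, `run`).

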