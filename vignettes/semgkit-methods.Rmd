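---
title: "Methods: simulated sEMG posture recognition with semgkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated sEMG posture recognition with semgkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(semgkit)
```

This vignette is the package's account of its models and the choices behind
them: what is simulated and why, how each pipeline stage is defined, which
parameters matter, and what the passing test suite does and does not
establish about real recordings.

## The signal model

Surface EMG during a held contraction is well described, at the electrode
level, as amplitude-modulated band-limited Gaussian noise: the interference
pattern of many asynchronous motor-unit action potentials. `semgkit`'s
generator adopts exactly this engineering model and deliberately nothing
deeper — no motor-unit pool, no force dynamics, no fatigue, no electrode
shift. Channel $c$ of a trial of posture $p$ is

$$x_c(t) = a_{pc} \, e^{\varepsilon_c} \, g_c(t), \qquad
  \varepsilon_c \sim \mathcal N(0, \sigma_d^2),$$

where $g_c$ is unit-RMS Gaussian noise band-passed (4th-order Butterworth)
around a per-posture, per-channel centre frequency with relative bandwidth
0.6, $a_{pc}$ is the entry of a postures × channels activation matrix, and
$\sigma_d$ is the dispersion of training day $d$. The carrier is normalised
to unit RMS over the trial, so the realised trial RMS equals its target
exactly and the dispersion knob is recoverable from data (the tests check
both). Channels are then mixed by the crosstalk matrix with $1-\lambda$ on
the diagonal and $\lambda/(C-1)$ off it — row-stochastic, so a
channel-constant signal passes unchanged.

Two modelling decisions deserve emphasis:

- **The training effect is amplitude-dispersion shrinkage and nothing
  else.** Biofeedback training is modelled by a decreasing per-day schedule
  $\sigma_d$ (default 0.5, 0.25, 0.1 over three days; the shipped amputee
  scenario uses a gentler five-day schedule starting higher). There are no
  within-day adaptation dynamics.
- **The dispersion draw is per channel, not per trial.** A single shared
  $\varepsilon$ per trial would rescale the whole activation vector, leaving
  its *direction* — which is what both the classifier and the silhouette
  respond to — untouched; per-channel draws perturb the pattern shape, which
  is the phenomenon the variability-reduction story is about.

The default 12 × 9 activation matrix has deliberate block structure: the
cylindrical/spherical grasp rows and the palmar/tip pinch rows are nearly
parallel, making those the two hardest pairs, while their spectral centroids
differ, so the frequency-sensitive features genuinely help. The shipped
amputee configuration is an *illustrative synthetic scenario* of an
eight-channel residual-limb montage, not a reconstruction of any person's
statistics; `amputee_mode()` separately lets you delete channels from any
configuration to study information loss (the deleted-channel confusion
structure is an acceptance property).

## Conditioning and windowing

Recordings are band-passed per channel with a 4th-order Butterworth,
10–500 Hz by default (Nyquist-checked against the sampling rate, 1926 Hz in
the reference protocol). Filtering is zero-phase (forward–backward) because
the analysis is offline; a `causal` flag switches to a single pass for
real-time emulation. A note on flatness: re-applying the band-pass to its
own white-noise output still removes ~3.5% RMS, because transition-band
energy is attenuated again on every pass. This is a property of any finite-
order filter, so the suite states flatness the meaningful way — noise
confined to 50–400 Hz, well inside the passband, re-filters with under 2%
RMS change.

Window length and overlap are free parameters with defaults of 250 ms and
50%, the usual compromise between feature stability and control latency in
myoelectric interfaces, and 0.5 s is trimmed from each trial end to drop
posture-transition ramps; all three are configurable and none is claimed to
be canonical. Window length in samples is `round(length_ms · fs / 1000)`,
the hop is `floor(N · (1 − overlap))` (minimum 1), and a trailing partial
window is discarded — the count is pinned to a brute-force enumeration in
the tests.

## Features and the threshold grid

The four time-domain features are computed exactly as defined (MAV, WL, and
the gated ZC and SSC counts; the SSC indicator is applied to the product of
adjacent slopes, with ≥ comparisons, so exact zeros count). The ZC gate
reads as sign opposition *and* jump magnitude `|x_i − x_{i+1}| ≥ T`; the
absolute value matters, since a signed gate would make the count depend on
crossing direction. The gate `T = R · RMS(rest)` is calibrated per channel
from rest trials, with `R` on the 21-point grid 0–10 by 0.5. When data
spanning several sessions are available, `optimize_R()` sweeps the grid with
held-out-session validation accuracy as the criterion and breaks ties toward
smaller `R`; one shared `R` serves both ZC and SSC (a per-feature override
exists). Internally the extractor uses a prefix-sum formulation over each
channel's full signal — O(samples) per channel rather than per window — and
the suite asserts cell-for-cell equality with the scalar definitions.

Feature columns are z-scored before classification using statistics of the
training fold only, stored with the model.

## Classifier and cross-testing

The classifier is a single-hidden-layer perceptron (`nnet`, BFGS, weight
decay 1e-3) with early stopping scored on a stratified 15% validation split
carved from the training windows; training proceeds in warm-started chunks
of 100 iterations (budget 200) and keeps the best-scoring weights. The
default hidden layer is 24 units: at the shipped-fixture scale (3600
windows × 36 features, 12 classes) a 64-unit net took an order of magnitude
longer to fit *and* tested worse — the small net is the better-regularised
choice for feature vectors this compact. Everything is configurable and
recorded in the evaluation metadata.

Cross-testing is session-wise: at level TRNk, fold $f$ of 10 trains on the
k contiguous sessions starting at $f$ (wrapping) and tests on the other
10−k, so each session is tested exactly 10−k times. Contiguous rotation was
chosen over random subsets for determinism and exhaustiveness. Threshold
calibration and normalisation happen strictly inside the fold's training
sessions — the suite asserts bit-identical training artifacts after
corrupting every test-session sample. Scoring is per window by default;
`vote = "trial"` aggregates a trial's windows by majority with mean-
posterior tie-breaks, since either granularity is defensible and they are
reported separately.

## Silhouettes, SC and the embedding

Cluster variability is quantified on the per-window MAV vectors (one
dimension per channel) — raw samples at 1926 Hz would be computationally
meaningless as points, and MAV is the amplitude pattern the radar feedback
displays. Distances are Mahalanobis under a single covariance pooled over
all points with shrinkage $\gamma = 0.1$ toward the scaled identity
($\hat\Sigma = (1-\gamma)S + \gamma\,\mathrm{tr}(S)/d\,I$): pooled, because
per-cluster covariances go singular for tight clusters; shrunk, because
near-collinear feature columns otherwise blow up the inverse. With identity
covariance the distance reduces exactly to Euclidean (tested to 1e-12).

Per-point silhouettes follow the standard definition with the singleton
branch ($s_i = 0$ when the point's cluster has size 1). The headline
statistic is $SC = \max_J \bar s_J$, the *maximum* per-cluster mean — an
unusual aggregation, kept deliberately because it is the one this analysis
tradition reports; since most of the literature uses the all-point mean,
that value is always reported alongside. The package makes no attempt to
match any particular published SC magnitude: what it asserts, and what the
acceptance suite verifies, is the *monotone response* — shrinking the
simulator's dispersion schedule strictly raises SC day over day.

The 2-D embedding delegates to the standard t-SNE implementation (`Rtsne`),
seeded and centred; the package treats it as a visualisation contract
(deterministic, structure-preserving on well-separated blobs), not a
statistic.

## Radar patterns and the match score

The feedback target for a posture is its per-channel mean MAV normalised by
the maximum channel — normalising by the maximum rather than the sum keeps
the radar *shape* amplitude-free, which is how a user visually compares
patterns. The live match score is the cosine similarity clipped to [0, 1]:
1 exactly when the live pattern is a positive multiple of the target, 0 for
orthogonal or absent activation. The interactive GUI of a feedback rig is
out of scope; the computational core (target, score, static export) is what
the package provides.

## Problem sizes and numerical choices

The shipped healthy fixture is the full reference geometry: 12 postures ×
10 sessions × 3 days, 5 s trials at 1926 Hz, nine channels — 390 trials and
10,800 analysis windows. The acceptance checks run the complete pipeline at
this scale; unit tests use smaller geometries (3–5 channels, 1–2 s trials,
lower rates) chosen to exercise the same code paths quickly. Elsewhere:
zero-variance feature columns get unit scale rather than dividing by zero;
`a_i = b_i = 0` silhouette points (duplicated across clusters) score 0; the
fold seed is derived arithmetically from the user seed so every fold is
independently reproducible; and all RNG use restores the caller's state.

## What passing tests do and do not show

The simulator produces what the pipeline assumes: stationary band-limited
trials, balanced sessions, a rest baseline, log-normal amplitude dispersion
that actually shrinks with training. Real recordings violate several of
these — electrode lift-off and shift, mains interference, fatigue drift
within a session, co-contraction structure beyond a fixed activation matrix,
and amputee signal statistics that no nine-parameter row can capture.
Passing the suite therefore certifies the *software* — formulas, fold
hygiene, determinism, monotone responses to known ground truth — not any
clinical claim about recognition accuracy or training efficacy in humans.
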