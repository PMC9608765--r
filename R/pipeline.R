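#' Full-experiment pipeline configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]: simulation,
#' band-pass conditioning, windowing, feature extraction, cross-testing and
#' cluster analysis. The defaults reproduce the shipped healthy-adult study
#' at full breadth (both feature sets, TRN1..TRN9 on every simulated day);
#' pass a reduced `trn_levels` / `synth` for quick runs.
#'
#' @param synth A [synth_config()].
#' @param filter A [filter_spec()].
#' @param window A [window_spec()].
#' @param classifier A [classifier_spec()].
#' @param feature_sets Feature sets to evaluate.
#' @param R Threshold multiplier for the Hudgins set.
#' @param trn_levels TRN levels to cross-test.
#' @param metric Distance metric for the silhouette analysis.
#' @param shrinkage Covariance shrinkage for the Mahalanobis metric.
#' @param seed Master seed for classifier training (the simulator uses
#'   `synth$seed`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = healthy_fixture_config(),
                            filter = filter_spec(),
                            window = window_spec(),
                            classifier = classifier_spec(),
                            feature_sets = c("hudgins", "mav"),
                            R = 2, trn_levels = 1:9,
                            metric = "mahalanobis", shrinkage = 0.1,
                            seed = 1L) {
  structure(list(synth = synth, filter = filter, window = window,
                 classifier = classifier, feature_sets = feature_sets,
                 R = R, trn_levels = as.integer(trn_levels), metric = metric,
                 shrinkage = shrinkage, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full synthetic experiment end to end
#'
#' Orchestrates simulate -> band-pass filter -> window -> features ->
#' session-wise cross-testing -> silhouette analysis -> radar patterns. The
#' report is a deterministic function of the configuration; when `out_dir`
#' is given, the accuracy table, per-day confusion matrices, silhouette
#' summary, radar patterns and a manifest (the exact configuration and
#' seeds) are written there as CSV/JSON.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional results directory.
#' @param verbose Log stage progress to stderr.
#' @return Object of class `semg_report`: `accuracy` (long data.frame),
#'   `silhouette` (per-day SC data.frame), `evals` (list of `semg_eval`),
#'   `patterns` (final-day radar patterns), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[semgkit] ", ...)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  say("simulating ", length(config$synth$sigma_trial), " day(s)")
  sim <- stage("simulate", generate_dataset(config$synth))
  say("filtering ", length(sim$recordings), " trials")
  recs <- stage("filter",
                lapply(sim$recordings, bandpass_filter, spec = config$filter))
  days <- sort(unique(vapply(recs, `[[`, integer(1), "day_id")))
  evals <- list()
  sil <- data.frame(day = integer(), SC = numeric(), mean_s = numeric())
  for (d in days) {
    drecs <- Filter(function(r) r$day_id == d, recs)
    say("day ", d, ": silhouette analysis")
    ps <- stage("silhouette", {
      f <- extract_features(
        segment_dataset(Filter(function(r) r$posture != REST_CAL_LABEL, drecs),
                        config$window),
        feature_config("mav"))
      m <- mav_point_set(f)
      silhouette_coefficient(m$points, m$labels, metric = config$metric,
                             shrinkage = config$shrinkage)
    })
    sil <- rbind(sil, data.frame(day = d, SC = ps$SC, mean_s = ps$mean_s))
    for (fs in config$feature_sets) {
      for (k in config$trn_levels) {
        say("day ", d, ": TRN", k, " (", fs, ")")
        ev <- stage(paste0("crosstest day ", d, " TRN", k, " ", fs),
                    cross_test(drecs, k, feature_set = fs, R = config$R,
                               classifier_spec = config$classifier,
                               window_spec = config$window,
                               seed = config$seed + 1000L * d + 10L * k,
                               n_sessions = config$synth$sessions_per_day))
        evals[[length(evals) + 1L]] <- ev
      }
    }
  }
  final_day <- max(days)
  say("radar patterns from day ", final_day)
  patterns <- stage("radar", {
    frecs <- Filter(function(r)
      r$day_id == final_day & r$posture != REST_CAL_LABEL, recs)
    lapply(stats::setNames(nm = config$synth$postures), function(p)
      compute_target_pattern(frecs, p, config$window))
  })
  report <- structure(list(accuracy = accuracy_trend(evals),
                           silhouette = sil, evals = evals,
                           patterns = patterns, config = config),
                      class = "semg_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.semg_report <- function(x, ...) {
  cat(sprintf("<semg_report> %d accuracy cells over %d day(s)\n",
              nrow(x$accuracy), nrow(x$silhouette)))
  cat("silhouette by day:\n")
  print(x$silhouette, row.names = FALSE)
  cat("accuracy (first rows):\n")
  print(utils::head(x$accuracy), row.names = FALSE)
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$accuracy, file.path(out_dir, "accuracy.csv"),
                   row.names = FALSE)
  utils::write.csv(report$silhouette, file.path(out_dir, "silhouette.csv"),
                   row.names = FALSE)
  for (ev in report$evals) {
    fn <- sprintf("confusion_day%d_trn%d_%s.csv", ev$day, ev$trn_level,
                  ev$feature_set)
    utils::write.csv(ev$confusion, file.path(out_dir, fn))
  }
  for (p in report$patterns) {
    render_radar(p, file.path(out_dir, sprintf(
      "radar_%s.csv", gsub("[^a-z0-9]+", "_", tolower(p$posture)))))
  }
  cfg <- report$config
  manifest <- list(
    format_version = MANIFEST_VERSION,
    seed = cfg$seed,
    synth = list(n_channels = cfg$synth$n_channels,
                 postures = cfg$synth$postures,
                 sigma_trial = cfg$synth$sigma_trial,
                 crosstalk_lambda = cfg$synth$crosstalk_lambda,
                 rest_amplitude = cfg$synth$rest_amplitude,
                 fs = cfg$synth$fs, trial_s = cfg$synth$trial_s,
                 sessions_per_day = cfg$synth$sessions_per_day,
                 seed = cfg$synth$seed,
                 amplitude_matrix = as.numeric(cfg$synth$amplitude_matrix),
                 spectral_centroid_matrix =
                   as.numeric(cfg$synth$spectral_centroid_matrix),
                 channel_names = cfg$synth$channel_names),
    filter = unclass(cfg$filter), window = unclass(cfg$window),
    classifier = unclass(cfg$classifier),
    feature_sets = cfg$feature_sets, R = cfg$R,
    trn_levels = cfg$trn_levels, metric = cfg$metric,
    shrinkage = cfg$shrinkage)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Rebuild a pipeline configuration from a written manifest
#'
#' Reads the `manifest.json` emitted by [run_pipeline()] and reconstructs the
#' exact [pipeline_config()] (including every seed), so a results directory
#' can be reproduced bit for bit from its manifest alone.
#'
#' @param path Path to a pipeline `manifest.json`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_manifest <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- j$synth
  synth <- synth_config(
    n_channels = s$n_channels, postures = s$postures,
    amplitude_matrix = matrix(s$amplitude_matrix, length(s$postures),
                              s$n_channels,
                              dimnames = list(s$postures, s$channel_names)),
    spectral_centroid_matrix = matrix(s$spectral_centroid_matrix,
                                      length(s$postures), s$n_channels),
    sigma_trial = s$sigma_trial, crosstalk_lambda = s$crosstalk_lambda,
    rest_amplitude = s$rest_amplitude, fs = s$fs, trial_s = s$trial_s,
    sessions_per_day = s$sessions_per_day, seed = s$seed,
    channel_names = s$channel_names)
  pipeline_config(
    synth = synth,
    filter = filter_spec(j$filter$low_hz, j$filter$high_hz, j$filter$order,
                         j$filter$causal),
    window = window_spec(j$window$length_ms, j$window$overlap_fraction,
                         j$window$trim_s),
    classifier = classifier_spec(j$classifier$hidden, j$classifier$max_epochs,
                                 j$classifier$patience,
                                 j$classifier$chunk_epochs,
                                 j$classifier$validation_fraction,
                                 j$classifier$decay),
    feature_sets = j$feature_sets, R = j$R, trn_levels = j$trn_levels,
    metric = j$metric, shrinkage = j$shrinkage, seed = j$seed)
}
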