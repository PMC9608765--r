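#' Radar-plot target pattern for a posture
#'
#' The visual-feedback target: per-channel mean MAV over every analysis
#' window of the posture's trials, normalised by the maximum channel so the
#' radar shape is amplitude-scale-free (max axis = 1 for any non-silent
#' posture).
#'
#' @param recordings Filtered [semg_recording()] list containing at least one
#'   trial of `posture`.
#' @param posture Posture label.
#' @param window_spec A [window_spec()].
#' @return Object of class `radar_pattern`: `posture`, `values` (named
#'   per-channel vector in \[0, 1\]), `channel_names`.
#' @export
compute_target_pattern <- function(recordings, posture,
                                   window_spec = semgkit::window_spec()) {
  sel <- Filter(function(r) r$posture == posture, recordings)
  if (!length(sel))
    stop("no trials of posture '", posture, "' in the dataset", call. = FALSE)
  f <- extract_features(segment_dataset(sel, window_spec),
                        feature_config("mav"))
  v <- colMeans(f$x)
  names(v) <- sel[[1L]]$channel_names
  if (max(v) > 0) {
    v <- v / max(v)
  } else {
    warning("all-zero activation for posture '", posture, "'", call. = FALSE)
  }
  structure(list(posture = posture, values = v,
                 channel_names = sel[[1L]]$channel_names),
            class = "radar_pattern")
}

#' @export
print.radar_pattern <- function(x, ...) {
  cat(sprintf("<radar_pattern> '%s' over %d channels\n", x$posture,
              length(x$values)))
  print(round(x$values, 3))
  invisible(x)
}

#' Score a live MAV vector against a radar target pattern
#'
#' Cosine similarity between the live per-channel MAV vector and the target
#' pattern, clipped to \[0, 1\]: 1 iff the live pattern is a positive scalar
#' multiple of the target, 0 for orthogonal (or absent) activation. The
#' per-channel deviations of the max-normalised live pattern from the target
#' are returned for axis-level feedback.
#'
#' @param live_window_mav Per-channel MAV vector from the current window.
#' @param target A `radar_pattern`.
#' @return Object of class `match_score`: `score` in \[0, 1\], `deviation`
#'   per channel, and a `no_activation` flag.
#' @export
match_score <- function(live_window_mav, target) {
  stopifnot(inherits(target, "radar_pattern"))
  v <- as.numeric(live_window_mav)
  t <- as.numeric(target$values)
  if (length(v) != length(t))
    stop("live vector length (", length(v), ") does not match the target (",
         length(t), ")", call. = FALSE)
  if (all(t == 0)) stop("target pattern is all-zero", call. = FALSE)
  if (all(v == 0)) {
    return(structure(list(score = 0, deviation = -t, no_activation = TRUE),
                     class = "match_score"))
  }
  cs <- sum(v * t) / (sqrt(sum(v^2)) * sqrt(sum(t^2)))
  structure(list(score = min(1, max(0, cs)),
                 deviation = v / max(v) - t, no_activation = FALSE),
            class = "match_score")
}

#' @export
print.match_score <- function(x, ...) {
  cat(sprintf("<match_score> %.3f%s\n", x$score,
              if (x$no_activation) " (no activation)" else ""))
  invisible(x)
}

#' Export a radar pattern as CSV and (optionally) a figure
#'
#' Always writes the raw axis values as a two-column CSV (channel, value) so
#' the pattern is testable headlessly; when `out_path` ends in `.svg`, `.pdf`
#' or `.png`, the polar polygon is drawn there and the CSV is written
#' alongside with the extension swapped for `.csv`.
#'
#' @param pattern A `radar_pattern`.
#' @param out_path Destination path (`.csv`, `.svg`, `.pdf` or `.png`).
#' @return Path of the written CSV, invisibly.
#' @export
render_radar <- function(pattern, out_path) {
  stopifnot(inherits(pattern, "radar_pattern"))
  ext <- tolower(tools::file_ext(out_path))
  csv_path <- if (ext == "csv") out_path else
    paste0(tools::file_path_sans_ext(out_path), ".csv")
  utils::write.csv(data.frame(channel = names(pattern$values),
                              value = unname(pattern$values)),
                   csv_path, row.names = FALSE)
  if (ext %in% c("svg", "pdf", "png")) {
    switch(ext,
           svg = grDevices::svg(out_path, width = 5, height = 5),
           pdf = grDevices::pdf(out_path, width = 5, height = 5),
           png = grDevices::png(out_path, width = 600, height = 600))
    on.exit(grDevices::dev.off())
    plot(pattern)
  }
  invisible(csv_path)
}

#' Plot a radar pattern as a polar polygon
#'
#' One axis per channel (in channel order), radii in \[0, 1\], axes labelled
#' with the muscle names.
#'
#' @param x A `radar_pattern`.
#' @param ... Unused.
#' @export
plot.radar_pattern <- function(x, ...) {
  v <- unname(x$values)
  C <- length(v)
  theta <- pi / 2 - 2 * pi * (seq_len(C) - 1L) / C  # clockwise from 12 o'clock
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1, axes = FALSE,
       xlab = "", ylab = "", main = x$posture)
  for (r in c(0.25, 0.5, 0.75, 1)) {
    graphics::polygon(r * cos(theta), r * sin(theta), border = "grey80")
  }
  graphics::segments(0, 0, cos(theta), sin(theta), col = "grey80")
  graphics::polygon(v * cos(theta), v * sin(theta),
                    border = "steelblue", col = grDevices::adjustcolor(
                      "steelblue", alpha.f = 0.35), lwd = 2)
  graphics::text(1.18 * cos(theta), 1.18 * sin(theta), names(x$values),
                 cex = 0.8)
  invisible(x)
}
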