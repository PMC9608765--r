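#' Save a collection of recordings as delimited files plus a JSON manifest
#'
#' Each trial is written as a headerless CSV (one row per time sample, one
#' column per channel) alongside a versioned JSON manifest holding subject,
#' sampling rate, channel names and per-trial metadata. The format round-trips
#' bit-exactly through [load_dataset()].
#'
#' @param recordings List of [semg_recording()] objects sharing `fs`,
#'   `subject_id` and `channel_names`.
#' @param root_path Directory to write into (created if absent).
#' @return Path of the written manifest, invisibly.
#' @export
save_dataset <- function(recordings, root_path) {
  if (!length(recordings)) {
    dir.create(root_path, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(format_version = MANIFEST_VERSION,
                     subject_id = "none", fs_hz = NA, channel_names = character(),
                     trials = list())
    mp <- file.path(root_path, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(mp))
  }
  for (r in recordings) validate_recording(r)
  fss <- vapply(recordings, function(r) r$fs, numeric(1))
  if (length(unique(fss)) != 1L)
    stop("recordings have inconsistent sampling rates: ",
         paste(unique(fss), collapse = ", "), call. = FALSE)
  chs <- unique(vapply(recordings, function(r)
    paste(r$channel_names, collapse = "|"), character(1)))
  if (length(chs) != 1L)
    stop("recordings have heterogeneous channel sets", call. = FALSE)
  dir.create(root_path, recursive = TRUE, showWarnings = FALSE)
  trials <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    r <- recordings[[i]]
    fn <- sprintf("trial_%04d.csv", i)
    # full binary precision so load(save(x)) is bit-identical
    utils::write.table(
      format(t(r$samples), digits = 17, trim = TRUE, scientific = TRUE),
      file.path(root_path, fn),
      sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
    trials[[i]] <- list(file = fn, posture = r$posture,
                        session_id = r$session_id, day_id = r$day_id)
  }
  manifest <- list(format_version = MANIFEST_VERSION,
                   subject_id = recordings[[1L]]$subject_id,
                   fs_hz = recordings[[1L]]$fs,
                   channel_names = recordings[[1L]]$channel_names,
                   trials = trials)
  mp <- file.path(root_path, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(mp)
}

MANIFEST_VERSION <- "1.0"

#' Load a dataset written by [save_dataset()]
#'
#' Reads the JSON manifest and every referenced trial file; fails atomically
#' (either the whole dataset loads or an error names the offending file or
#' label, and nothing is returned).
#'
#' @param root_path Directory containing `manifest.json` and trial CSVs.
#' @return List of [semg_recording()] objects (possibly empty, with a warning).
#' @export
load_dataset <- function(root_path) {
  mp <- file.path(root_path, "manifest.json")
  if (!file.exists(mp))
    stop("no manifest.json found under '", root_path, "'", call. = FALSE)
  manifest <- jsonlite::read_json(mp, simplifyVector = FALSE)
  trials <- manifest$trials
  if (!length(trials)) {
    warning("dataset at '", root_path, "' contains no trials", call. = FALSE)
    return(list())
  }
  channel_names <- unlist(manifest$channel_names)
  out <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    fp <- file.path(root_path, tr$file)
    if (!file.exists(fp))
      stop("trial file missing: '", fp, "'", call. = FALSE)
    m <- as.matrix(utils::read.table(fp, sep = ",", header = FALSE,
                                     colClasses = "numeric"))
    dimnames(m) <- NULL
    if (ncol(m) != length(channel_names))
      stop("'", fp, "' has ", ncol(m), " columns but the manifest names ",
           length(channel_names), " channels", call. = FALSE)
    out[[i]] <- semg_recording(
      samples = t(m), fs = manifest$fs_hz, posture = tr$posture,
      session_id = tr$session_id, day_id = tr$day_id,
      subject_id = manifest$subject_id, channel_names = channel_names)
  }
  out
}
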