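#' Write a bundle as an OpenFace-style per-frame CSV
#'
#' Columns (bit-exact header names, so real OpenFace output is readable by
#' the same reader): `frame`, `timestamp`, `confidence`, `success`, the
#' three pose rotation columns `pose_Rx`, `pose_Ry`, `pose_Rz`, then one
#' `AUxx_r` intensity column per AU channel. Frame numbers are 1-based;
#' timestamps in seconds.
#'
#' @param bundle a [ts_bundle()] containing pose and AU channels.
#' @param path output file.
#' @param confidence per-frame confidence written for valid frames
#'   (invalid frames get 0 confidence and success 0).
#' @return invisibly, `path`.
#' @export
write_openface_csv <- function(bundle, path, confidence = 0.98) {
  au_cols <- sort(grep("^AU\\d+_r$", names(bundle$channels), value = TRUE))
  pose_cols <- c("pose_Rx", "pose_Ry", "pose_Rz")
  missing_pose <- setdiff(pose_cols, names(bundle$channels))
  if (length(missing_pose))
    stop_arg("bundle lacks pose channel(s): %s",
             paste(missing_pose, collapse = ", "))
  n <- length(bundle$channels[[1]])
  valid <- Reduce(`&`, lapply(bundle$channels[c(pose_cols, au_cols)],
                              function(ch) ch$valid))
  df <- data.frame(frame = seq_len(n),
                   timestamp = (seq_len(n) - 1) / bundle$fps,
                   confidence = ifelse(valid, confidence, 0),
                   success = as.integer(valid))
  for (cl in pose_cols) df[[cl]] <- bundle$channels[[cl]]$values
  for (cl in au_cols) df[[cl]] <- bundle$channels[[cl]]$values
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an OpenFace-style per-frame CSV into a bundle
#'
#' Reads `pose_R*` and `AU*_r` columns into channels. Frames with
#' `success == 0` are marked invalid in every channel; the raw confidence
#' column is kept as a `confidence` channel for [preprocess_series()].
#'
#' @param path CSV file.
#' @param participant_id,task identifiers for the bundle.
#' @param fps frame rate; inferred from the `timestamp` column when
#'   possible.
#' @return a [ts_bundle()].
#' @export
read_openface_csv <- function(path, participant_id = "unknown",
                              task = "unknown", fps = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  names(df) <- trimws(names(df))
  if (is.null(fps)) {
    fps <- if ("timestamp" %in% names(df) && nrow(df) > 1L) {
      dt <- stats::median(diff(df$timestamp))
      if (is.finite(dt) && dt > 0) 1 / dt else 30
    } else 30
  }
  valid <- if ("success" %in% names(df)) df$success == 1 else
    rep(TRUE, nrow(df))
  wanted <- grep("^(pose_R[xyz]|AU\\d+_r)$", names(df), value = TRUE)
  if (length(wanted) == 0L)
    stop_arg("no pose_R* or AU*_r columns found in %s", path)
  channels <- lapply(wanted, function(cl)
    channel_series(df[[cl]], fps = fps, name = cl, valid = valid))
  names(channels) <- wanted
  if ("confidence" %in% names(df))
    channels$confidence <- channel_series(df$confidence, fps = fps,
                                          name = "confidence")
  ts_bundle(participant_id, task, channels)
}

#' Write motion-energy series as an MEA-style CSV
#'
#' One column per ROI, one row per frame; headerless by default, matching
#' the common MEA export convention.
#'
#' @param series named list of [channel_series()] (or a single one).
#' @param path output file.
#' @param header write column names (default `FALSE`).
#' @return invisibly, `path`.
#' @export
write_mea_csv <- function(series, path, header = FALSE) {
  if (inherits(series, "channel_series")) series <- list(series)
  df <- as.data.frame(lapply(series, function(ch) ch$values))
  names(df) <- vapply(series, function(ch) ch$name, character(1))
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = header, qmethod = "double")
  invisible(path)
}

#' Read an MEA-style CSV
#'
#' @param path CSV file, one ROI per column, one frame per row.
#' @param fps frame rate of the recording.
#' @param col_names ROI names; required when the file is headerless
#'   (default `"roi1"`, `"roi2"`, ...).
#' @param header whether the file has a header row (default `FALSE`).
#' @return named list of [channel_series()].
#' @export
read_mea_csv <- function(path, fps = 30, col_names = NULL, header = FALSE) {
  df <- utils::read.csv(path, header = header)
  if (!header) {
    if (is.null(col_names)) col_names <- sprintf("roi%d", seq_along(df))
    names(df) <- col_names
  }
  out <- lapply(names(df), function(nm)
    channel_series(df[[nm]], fps = fps, name = nm))
  stats::setNames(out, names(df))
}

#' Write / read a dyad roster as CSV
#'
#' The participant-record fields round-trip; the dyad-type map is
#' reconstructed from the diagnoses (a dyad is mixed iff exactly one member
#' has an ASD diagnosis).
#'
#' @param roster a `dyad_roster`.
#' @param path CSV file.
#' @return `write_roster_csv`: invisibly, `path`; `read_roster_csv`: a
#'   `dyad_roster`.
#' @export
write_roster_csv <- function(roster, path) {
  utils::write.csv(as.data.frame(roster), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roster_csv
#' @export
read_roster_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$excluded <- as.logical(df$excluded)
  df$exclusion_reason <- as.character(df$exclusion_reason)
  tp <- vapply(unique(df$dyad_id), function(d) {
    diag <- df$diagnosis[df$dyad_id == d]
    if (sum(diag == "ASD") == 1L) "mixed" else "control"
  }, character(1))
  new_roster(df, tp)
}

#' Write a long-format synchrony summary CSV
#'
#' @param sync the `sync` data frame from [compute_sync_features()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_sync_csv <- function(sync, path) {
  utils::write.csv(sync, path, row.names = FALSE)
  invisible(path)
}

#' Write a feature matrix (with labels) as CSV
#'
#' Participants as rows (first column `participant`), one named column per
#' feature, and a final `label` column.
#'
#' @param features a `feature_set`.
#' @param labels a `label_vector`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_feature_csv <- function(features, labels, path) {
  m <- features$matrix
  df <- data.frame(participant = rownames(m), m, check.names = FALSE,
                   row.names = NULL)
  df$label <- as.character(labels$labels[rownames(m)])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
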