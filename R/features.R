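#' Global head movement from the three rotation channels
#'
#' Per frame, the Euclidean norm of the frame-to-frame change of the
#' (pitch, yaw, roll) head rotation vector; the first frame is 0. A frame is
#' valid when all three pose channels are valid at it and at the preceding
#' frame.
#'
#' @param pitch,yaw,roll [channel_series()] of equal length.
#' @return a [channel_series()] named `"head_movement"`.
#' @export
global_head_movement <- function(pitch, yaw, roll) {
  n <- length(pitch)
  if (length(yaw) != n || length(roll) != n)
    stop_arg("pose channel lengths differ: %d/%d/%d",
             n, length(yaw), length(roll))
  gm <- c(0, sqrt(diff(pitch$values)^2 + diff(yaw$values)^2 +
                    diff(roll$values)^2))
  v <- pitch$valid & yaw$valid & roll$valid
  valid <- v & c(v[1], v[-n])
  channel_series(gm, fps = pitch$fps, name = "head_movement", valid = valid,
                 usable = pitch$usable && yaw$usable && roll$usable)
}

#' Mean facial expressiveness over retained action units
#'
#' Mean AU intensity over valid frames and usable retained channels: one
#' scalar per participant and task.
#'
#' @param au_channels list of [channel_series()].
#' @return scalar; `NA` when no channel is usable.
#' @export
facial_expressiveness <- function(au_channels) {
  usable <- Filter(function(ch) ch$usable && any(ch$valid), au_channels)
  if (length(usable) == 0L) return(NA_real_)
  mean(vapply(usable, function(ch) mean(ch$values[ch$valid]), numeric(1)))
}

#' Total movement rate of a channel
#'
#' Sum of values over valid frames divided by the number of valid frames —
#' a per-frame rate, so partial tracking loss does not deflate the measure.
#'
#' @param series a [channel_series()].
#' @return scalar; `NA` when the channel is unusable or has no valid frame.
#' @export
total_movement <- function(series) {
  if (!series$usable || !any(series$valid)) return(NA_real_)
  sum(series$values[series$valid]) / sum(series$valid)
}

head_channel_set <- function() c("head_movement", "pose_Rx", "pose_Ry",
                                 "pose_Rz")

feature_name <- function(channel, task, statistic)
  paste(channel, task, statistic, sep = ".")

#' Parse a feature column name back into its parts
#'
#' @param name feature name produced by the assembly step
#'   (`channel.task.statistic`).
#' @return data frame with columns `channel`, `task`, `statistic`.
#' @export
parse_feature_name <- function(name) {
  parts <- strsplit(name, ".", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad))
    stop_arg("not a feature name: %s", paste(name[bad], collapse = ", "))
  data.frame(channel = vapply(parts, `[`, "", 1L),
             task = vapply(parts, `[`, "", 2L),
             statistic = vapply(parts, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

#' Compute all synchrony summaries and movement scalars for a study
#'
#' The pipeline glue between raw bundles and feature assembly. For every
#' dyad, task and channel it computes each member's following summary
#' (interpersonal), the member's intrapersonal head-body summary, and the
#' movement/expressiveness scalars.
#'
#' @param bundles nested list `bundles[[participant_id]][[task]]` of
#'   [ts_bundle()], as from [simulate_study()].
#' @param roster a finalized `dyad_roster`.
#' @param configs per-group [sync_config()]s, see [sync_default_configs()].
#' @param au_set retained AU channel names (default [default_au_set()]).
#' @param preprocess config from [preprocess_config()], applied to every
#'   channel (with the bundle's `confidence` channel when present).
#' @return list with `sync` (long data frame: participant, task, channel,
#'   direction, statistic, value) and `movement` (participant, task,
#'   measure, value).
#' @export
compute_sync_features <- function(bundles, roster,
                                  configs = NULL,
                                  au_set = default_au_set(),
                                  preprocess = preprocess_config()) {
  act <- active_roster(roster)
  fps <- bundles[[act$participant_id[1]]][[1]]$fps
  if (is.null(configs)) configs <- sync_default_configs(fps)
  tasks <- names(bundles[[act$participant_id[1]]])

  prep_bundle <- function(b) {
    conf <- b$channels[["confidence"]]
    b$channels <- lapply(b$channels, function(ch) {
      if (ch$name == "confidence") ch
      else preprocess_series(ch, confidence = conf, config = preprocess)
    })
    b
  }
  derive <- function(b) {
    b$channels$head_movement <- global_head_movement(
      b$channels$pose_Rx, b$channels$pose_Ry, b$channels$pose_Rz)
    b
  }

  sync_rows <- list()
  mov_rows <- list()
  add_sync <- function(pid, task, channel, direction, summary) {
    sync_rows[[length(sync_rows) + 1L]] <<- data.frame(
      participant = pid, task = task, channel = channel,
      direction = direction, statistic = names(unclass(summary)),
      value = as.numeric(summary), stringsAsFactors = FALSE)
  }

  for (d in unique(act$dyad_id)) {
    members <- act$participant_id[act$dyad_id == d]
    for (tk in tasks) {
      b1 <- derive(prep_bundle(bundles[[members[1]]][[tk]]))
      b2 <- derive(prep_bundle(bundles[[members[2]]][[tk]]))
      pair <- list(b1, b2)
      for (i in 1:2) {
        self <- pair[[i]]; partner <- pair[[3 - i]]
        pid <- members[i]
        for (ch in au_set)
          add_sync(pid, tk, ch, "following",
                   interpersonal_following_summary(self, partner, ch,
                                                   configs$face))
        for (ch in head_channel_set())
          add_sync(pid, tk, ch, "following",
                   interpersonal_following_summary(self, partner, ch,
                                                   configs$head))
        add_sync(pid, tk, "body", "following",
                 interpersonal_following_summary(self, partner, "body",
                                                 configs$body))
        add_sync(pid, tk, "head_body", "intrapersonal",
                 intrapersonal_summary(self$channels$head_movement,
                                       self$channels$body, configs$body))
        mov_rows[[length(mov_rows) + 1L]] <- data.frame(
          participant = pid, task = tk,
          measure = c("total_head", "total_body", "expressiveness"),
          value = c(total_movement(self$channels$head_movement),
                    total_movement(self$channels$body),
                    facial_expressiveness(self$channels[au_set])),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(sync = do.call(rbind, sync_rows), movement = do.call(rbind, mov_rows))
}

summary_stat_names <- function() c("mean", "median", "sd", "min", "max",
                                   "skewness", "kurtosis")

#' Assemble one of the five base-model feature sets
#'
#' Builds the participants x features matrix for a base model, combining
#' both conversation tasks per participant:
#' \describe{
#'   \item{FACEsync}{following summaries of the retained AU channels:
#'     12 AUs x 7 statistics x 2 tasks = 168 features.}
#'   \item{HEADsync}{following summaries of global head movement, pitch,
#'     yaw, roll: 4 x 7 x 2 = 56.}
#'   \item{BODYsync}{following summaries of body motion energy:
#'     1 x 7 x 2 = 14.}
#'   \item{INTRAsync}{intrapersonal head-body summaries: 1 x 7 x 2 = 14.}
#'   \item{MovEx}{total head movement, total body movement and facial
#'     expressiveness: 3 x 2 tasks = 6.}
#' }
#' Missing summary cells are preserved as `NA`; imputation happens inside
#' the cross-validated training loop only.
#'
#' @param model_name one of `"FACEsync"`, `"HEADsync"`, `"BODYsync"`,
#'   `"INTRAsync"`, `"MovEx"`.
#' @param roster a finalized `dyad_roster`.
#' @param sync_summaries,movement_scalars the two data frames from
#'   [compute_sync_features()] (`movement_scalars` needed for MovEx only).
#' @param au_set retained AU channels for FACEsync.
#' @param tasks task labels (columns exist for each).
#' @return an object of class `feature_set`: list with `matrix`
#'   (participants x features, row names = participant ids), `model_name`,
#'   `feature_names`, `expected_dim`.
#' @export
assemble_feature_set <- function(model_name, roster, sync_summaries,
                                 movement_scalars = NULL,
                                 au_set = default_au_set(),
                                 tasks = task_names()) {
  model_name <- match.arg(model_name, c("FACEsync", "HEADsync", "BODYsync",
                                        "INTRAsync", "MovEx"))
  act <- active_roster(roster)
  pids <- act$participant_id
  stats_n <- summary_stat_names()

  if (model_name == "MovEx") {
    if (is.null(movement_scalars))
      stop_arg("MovEx assembly needs `movement_scalars`")
    measures <- c("total_head", "total_body", "expressiveness")
    cols <- as.vector(outer(measures, tasks,
                            function(m, tk) feature_name(m, tk, "value")))
    mat <- matrix(NA_real_, length(pids), length(cols),
                  dimnames = list(pids, sort(cols)))
    key <- feature_name(movement_scalars$measure, movement_scalars$task,
                        "value")
    for (i in seq_len(nrow(movement_scalars))) {
      p <- movement_scalars$participant[i]
      if (p %in% pids && key[i] %in% colnames(mat))
        mat[p, key[i]] <- movement_scalars$value[i]
    }
    expected <- length(measures) * length(tasks)
  } else {
    spec <- switch(model_name,
      FACEsync = list(channels = au_set, direction = "following"),
      HEADsync = list(channels = head_channel_set(),
                      direction = "following"),
      BODYsync = list(channels = "body", direction = "following"),
      INTRAsync = list(channels = "head_body", direction = "intrapersonal"))
    grid <- expand.grid(channel = spec$channels, task = tasks,
                        statistic = stats_n, stringsAsFactors = FALSE)
    cols <- sort(feature_name(grid$channel, grid$task, grid$statistic))
    mat <- matrix(NA_real_, length(pids), length(cols),
                  dimnames = list(pids, cols))
    sel <- sync_summaries[sync_summaries$channel %in% spec$channels &
                            sync_summaries$direction == spec$direction &
                            sync_summaries$task %in% tasks, , drop = FALSE]
    key <- feature_name(sel$channel, sel$task, sel$statistic)
    keep <- sel$participant %in% pids
    mat[cbind(sel$participant[keep], key[keep])] <- sel$value[keep]
    expected <- length(spec$channels) * length(tasks) * length(stats_n)
  }
  if (ncol(mat) != expected)
    stop_arg("%s assembly produced %d columns, expected %d",
             model_name, ncol(mat), expected)
  structure(list(matrix = mat, model_name = model_name,
                 feature_names = colnames(mat), expected_dim = expected),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set %s> %d participants x %d features (%.1f%% missing)\n",
              x$model_name, nrow(x$matrix), ncol(x$matrix),
              100 * mean(is.na(x$matrix))))
  invisible(x)
}

#' Classification labels for a roster
#'
#' Under the default `dyad_type` scheme both interactants of a dyad receive
#' the same label — mixed (ASD-TD) or control (TD-TD) — mirroring a
#' diagnostic setting in which the classifier judges the interaction, not
#' the individual. The `diagnosis` scheme labels each participant by their
#' own diagnosis instead.
#'
#' @param roster a finalized `dyad_roster`.
#' @param scheme `"dyad_type"` (default) or `"diagnosis"`.
#' @return a `label_vector`: list with `labels` (named factor, positive
#'   class first), `scheme`, `positive_class`, `group` (named dyad id per
#'   participant).
#' @export
dyad_labels <- function(roster, scheme = c("dyad_type", "diagnosis")) {
  scheme <- match.arg(scheme)
  act <- active_roster(roster)
  tp <- dyad_types(roster)
  if (scheme == "dyad_type") {
    lab <- factor(unname(tp[act$dyad_id]), levels = c("mixed", "control"))
    pos <- "mixed"
  } else {
    lab <- factor(act$diagnosis, levels = c("ASD", "TD"))
    pos <- "ASD"
  }
  names(lab) <- act$participant_id
  structure(list(labels = lab, scheme = scheme, positive_class = pos,
                 group = stats::setNames(act$dyad_id, act$participant_id)),
            class = "label_vector")
}
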