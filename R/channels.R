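#' Per-frame behavioral channel
#'
#' A `channel_series` holds one per-frame signal for one participant and task:
#' an action-unit intensity, a head-pose angle, derived global head movement,
#' or a body motion-energy trace. Alongside the values it carries the frame
#' rate and a per-frame validity mask (e.g. tracking confidence below
#' threshold marks frames invalid).
#'
#' @param values numeric vector of per-frame values.
#' @param fps frames per second, > 0.
#' @param name channel name (e.g. `"AU12_r"`, `"pose_Rx"`, `"body"`).
#' @param valid logical vector, same length as `values`; defaults to all
#'   `TRUE`.
#' @param usable logical; set `FALSE` by preprocessing when the invalid
#'   fraction exceeds the exclusion threshold.
#' @return an object of class `channel_series`.
#' @export
channel_series <- function(values, fps, name = "channel", valid = NULL,
                           usable = TRUE) {
  values <- as.numeric(values)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop_arg("`fps` must be a single positive number")
  if (is.null(valid)) valid <- rep(TRUE, length(values))
  if (length(valid) != length(values))
    stop_arg("`valid` mask length (%d) != values length (%d)",
             length(valid), length(values))
  structure(
    list(values = values, fps = as.numeric(fps), name = as.character(name),
         valid = as.logical(valid), usable = isTRUE(usable)),
    class = "channel_series"
  )
}

#' @export
length.channel_series <- function(x) length(x$values)

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("<channel_series '%s'> %d frames @ %g fps, %.1f%% valid%s\n",
              x$name, length(x$values), x$fps,
              100 * mean(x$valid),
              if (x$usable) "" else " [UNUSABLE]"))
  invisible(x)
}

#' One participant x one task bundle of channels
#'
#' Collects all per-frame channels recorded for one participant during one
#' conversation task: action-unit intensities, the three head-pose rotation
#' angles, the derived global-head-movement channel, and the body
#' motion-energy channel.
#'
#' @param participant_id,task identifiers.
#' @param channels named list of [channel_series()] objects sharing one fps.
#' @return an object of class `ts_bundle`.
#' @export
ts_bundle <- function(participant_id, task, channels) {
  if (length(channels) == 0L) stop_arg("bundle needs at least one channel")
  if (is.null(names(channels)) || any(names(channels) == ""))
    stop_arg("`channels` must be a fully named list")
  fps <- unique(vapply(channels, function(ch) ch$fps, numeric(1)))
  if (length(fps) != 1L) stop_arg("all channels in a bundle must share one fps")
  structure(
    list(participant_id = as.character(participant_id),
         task = as.character(task), fps = fps, channels = channels),
    class = "ts_bundle"
  )
}

#' @export
print.ts_bundle <- function(x, ...) {
  cat(sprintf("<ts_bundle> participant %s, task '%s': %d channels x %d frames @ %g fps\n",
              x$participant_id, x$task, length(x$channels),
              length(x$channels[[1]]$values), x$fps))
  invisible(x)
}

bundle_channel <- function(bundle, name) {
  ch <- bundle$channels[[name]]
  if (is.null(ch))
    stop_arg("bundle for participant %s has no channel '%s'",
             bundle$participant_id, name)
  ch
}
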