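#' Region-of-interest specification
#'
#' Rectangular ROI in pixel coordinates, 0-based and half-open:
#' `[x0, x1) x [y0, y1)` with x running along columns and y along rows.
#'
#' @param label one of `"head"`, `"body"`, `"other"`.
#' @param x0,y0 top-left corner (inclusive), 0-based.
#' @param x1,y1 bottom-right corner (exclusive).
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(label = c("body", "head", "other"), x0, y0, x1, y1) {
  label <- match.arg(label)
  x0 <- check_count(x0, "x0"); y0 <- check_count(y0, "y0")
  x1 <- check_count(x1, "x1"); y1 <- check_count(y1, "y1")
  if (x1 <= x0 || y1 <= y0)
    stop_arg("roi must have positive extent: x1 > x0 and y1 > y0")
  structure(list(label = label, x0 = x0, y0 = y0, x1 = x1, y1 = y1),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec '%s'> [%d,%d) x [%d,%d)\n",
              x$label, x$x0, x$x1, x$y0, x$y1))
  invisible(x)
}

roi_pixels <- function(roi, frame) {
  if (roi$y1 > nrow(frame) || roi$x1 > ncol(frame))
    stop_arg("roi [%d,%d)x[%d,%d) out of bounds for %dx%d frame",
             roi$x0, roi$x1, roi$y0, roi$y1, nrow(frame), ncol(frame))
  list(rows = (roi$y0 + 1):roi$y1, cols = (roi$x0 + 1):roi$x1)
}

#' Convert a frame to grayscale
#'
#' Applies the ITU-R BT.601 luminance weighting
#' `0.299 R + 0.587 G + 0.114 B` to a `height x width x 3` color array;
#' grayscale matrices pass through unchanged (idempotent).
#'
#' @param frame numeric matrix (grayscale) or `h x w x 3` array (RGB),
#'   values on any consistent intensity scale (typically 0-255).
#' @return numeric matrix of luminance values.
#' @export
to_grayscale <- function(frame) {
  if (length(frame) == 0L) stop_arg("empty frame")
  if (is.matrix(frame)) return(frame)
  d <- dim(frame)
  if (length(d) == 3L && d[3] == 1L) return(frame[, , 1])
  if (length(d) != 3L || d[3] != 3L)
    stop_arg("frame must be a matrix or an h x w x 3 array")
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

#' Motion energy between two consecutive frames within an ROI
#'
#' Sums absolute grayscale pixel changes exceeding `noise_threshold` inside
#' the ROI; by default normalized by the ROI pixel count so differently sized
#' regions (head vs upper body) are comparable.
#'
#' @param prev,curr grayscale frames of identical shape.
#' @param roi an [roi_spec()] within frame bounds.
#' @param noise_threshold changes with `|curr - prev| <= noise_threshold` are
#'   suppressed (sensor-noise floor); default 10 gray levels.
#' @param normalize divide by ROI area (default `TRUE`); `FALSE` gives the
#'   raw sum.
#' @return nonnegative scalar energy.
#' @export
frame_difference_energy <- function(prev, curr, roi, noise_threshold = 10,
                                    normalize = TRUE) {
  prev <- to_grayscale(prev); curr <- to_grayscale(curr)
  if (!identical(dim(prev), dim(curr)))
    stop_arg("frame shape mismatch: %s vs %s",
             paste(dim(prev), collapse = "x"),
             paste(dim(curr), collapse = "x"))
  px <- roi_pixels(roi, prev)
  d <- abs(curr[px$rows, px$cols] - prev[px$rows, px$cols])
  e <- sum(d[d > noise_threshold])
  if (normalize) e / length(d) else e
}

#' Motion-energy time series for a frame stack
#'
#' Computes per-frame motion energy ([frame_difference_energy()]) for each
#' ROI across an ordered stack of frames. The first frame's energy is 0 by
#' convention (differencing loses one frame; the output stays aligned with
#' the input length).
#'
#' @param frames list of frames (grayscale matrices or RGB arrays), >= 2.
#' @param rois list of [roi_spec()] (a single `roi_spec` is accepted).
#' @param noise_threshold,normalize see [frame_difference_energy()].
#' @param fps frames per second recorded in the output series.
#' @return named list of [channel_series()], one per ROI (named by ROI
#'   label, disambiguated when labels repeat).
#' @export
motion_energy_series <- function(frames, rois, noise_threshold = 10,
                                 normalize = TRUE, fps = 30) {
  if (inherits(rois, "roi_spec")) rois <- list(rois)
  if (length(frames) < 2L) stop_arg("need at least 2 frames")
  gray <- lapply(frames, to_grayscale)
  out <- lapply(rois, function(roi) {
    e <- numeric(length(gray))
    for (t in 2:length(gray))
      e[t] <- frame_difference_energy(gray[[t - 1]], gray[[t]], roi,
                                      noise_threshold, normalize)
    channel_series(e, fps = fps, name = roi$label)
  })
  labs <- vapply(rois, function(r) r$label, character(1))
  names(out) <- make.unique(labs)
  out
}
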