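#' Windowed cross-lagged correlation configuration
#'
#' @param window_frames window length in frames (> 2).
#' @param step_frames hop between consecutive window starts, >= 1.
#' @param max_lag_frames maximum lag in frames; lags run from
#'   `-max_lag_frames` to `+max_lag_frames`. Must satisfy
#'   `window_frames >= 2 * max_lag_frames`.
#' @param min_valid_fraction minimum fraction of valid overlapping frame
#'   pairs for a window/lag cell to be computed (default 0.8).
#' @param peak_rule `"max_positive"` (most positive correlation; default) or
#'   `"max_absolute"` (signed value of largest magnitude).
#' @return an object of class `sync_config`.
#' @export
sync_config <- function(window_frames, step_frames, max_lag_frames,
                        min_valid_fraction = 0.8,
                        peak_rule = c("max_positive", "max_absolute")) {
  window_frames <- check_count(window_frames, "window_frames", min = 3L)
  step_frames <- check_count(step_frames, "step_frames", min = 1L)
  max_lag_frames <- check_count(max_lag_frames, "max_lag_frames", min = 0L)
  if (window_frames < 2L * max_lag_frames)
    stop_arg("window_frames (%d) must be >= 2 * max_lag_frames (%d)",
             window_frames, 2L * max_lag_frames)
  check_fraction(min_valid_fraction, "min_valid_fraction")
  if (min_valid_fraction <= 0) stop_arg("`min_valid_fraction` must be > 0")
  peak_rule <- match.arg(peak_rule)
  structure(list(window_frames = window_frames, step_frames = step_frames,
                 max_lag_frames = max_lag_frames,
                 min_valid_fraction = min_valid_fraction,
                 peak_rule = peak_rule),
            class = "sync_config")
}

#' Default synchrony configurations per channel group
#'
#' Facial and head channels use a 5 s window, 1 s step and +/- 2 s maximum
#' lag; the slower body motion-energy channel uses a 10 s window, 2 s step
#' and +/- 5 s lag. Values are conventions from the windowed cross-lagged
#' correlation literature and are fully configurable.
#'
#' @param fps frames per second used to convert seconds to frames.
#' @return named list of [sync_config()]: `face`, `head`, `body`.
#' @export
sync_default_configs <- function(fps = 30) {
  fast <- sync_config(window_frames = 5 * fps, step_frames = 1 * fps,
                      max_lag_frames = 2 * fps)
  list(face = fast, head = fast,
       body = sync_config(window_frames = 10 * fps, step_frames = 2 * fps,
                          max_lag_frames = 5 * fps))
}

#' Preprocessing configuration for raw channels
#'
#' @param confidence_threshold frames with tracking confidence below this are
#'   invalidated (default 0.8, the usual OpenFace cutoff).
#' @param max_gap_frames invalid gaps of at most this many frames, flanked by
#'   valid frames, are linearly interpolated and revalidated (default 10,
#'   i.e. a third of a second at 30 fps).
#' @param exclusion_threshold channels whose pre-interpolation invalid
#'   fraction exceeds this are flagged unusable (default 0.1).
#' @return a list config for [preprocess_series()].
#' @export
preprocess_config <- function(confidence_threshold = 0.8,
                              max_gap_frames = 10,
                              exclusion_threshold = 0.1) {
  list(confidence_threshold = confidence_threshold,
       max_gap_frames = check_count(max_gap_frames, "max_gap_frames"),
       exclusion_threshold = check_fraction(exclusion_threshold,
                                            "exclusion_threshold"))
}

#' Preprocess a raw channel: confidence gating, gap interpolation, usability
#'
#' Frames whose tracking confidence falls below the threshold are marked
#' invalid. Interior invalid gaps no longer than `max_gap_frames` are then
#' linearly interpolated between their valid neighbors and revalidated;
#' longer gaps (and invalid runs touching the series ends) stay invalid.
#' If the pre-interpolation invalid fraction exceeds the exclusion
#' threshold, the channel is flagged unusable — the extent of missingness,
#' not its reparability, decides exclusion. Nothing is ever silently
#' dropped.
#'
#' @param raw a [channel_series()].
#' @param confidence optional [channel_series()] of per-frame confidences.
#' @param config see [preprocess_config()].
#' @return a [channel_series()] with updated values, mask and `usable` flag.
#' @export
preprocess_series <- function(raw, confidence = NULL,
                              config = preprocess_config()) {
  valid <- raw$valid
  if (!is.null(confidence)) {
    if (length(confidence) != length(raw))
      stop_arg("confidence length (%d) != series length (%d)",
               length(confidence), length(raw))
    valid <- valid & (confidence$values >= config$confidence_threshold)
  }
  invalid_fraction <- mean(!valid)
  vals <- raw$values
  vals[!valid] <- NA_real_
  if (any(!valid) && any(valid)) {
    runs <- rle(valid)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (i in seq_along(runs$lengths)) {
      if (runs$values[i]) next
      if (i == 1L || i == length(runs$lengths)) next  # edge gaps stay invalid
      if (runs$lengths[i] > config$max_gap_frames) next
      a <- starts[i] - 1L; b <- ends[i] + 1L
      idx <- starts[i]:ends[i]
      vals[idx] <- vals[a] + (vals[b] - vals[a]) * (idx - a) / (b - a)
      valid[idx] <- TRUE
    }
  }
  channel_series(vals, fps = raw$fps, name = raw$name, valid = valid,
                 usable = raw$usable &&
                   invalid_fraction <= config$exclusion_threshold)
}

# window start indices (1-based) for the full-overlap policy: the y-segment
# at the extreme lags must lie entirely within the series
window_starts <- function(n, cfg) {
  first <- cfg$max_lag_frames + 1L
  last <- n - cfg$window_frames - cfg$max_lag_frames + 1L
  if (last < first) return(integer())
  seq.int(first, last, by = cfg$step_frames)
}

#' Windowed cross-lagged correlation matrix
#'
#' For each window start `s` (full-overlap policy: segments at the extreme
#' lags never run off the series) and each lag `k` in
#' `-max_lag .. +max_lag`, computes the Pearson correlation between
#' `x[s .. s+W-1]` and `y[s+k .. s+k+W-1]`. Sign convention, fixed
#' pipeline-wide: positive lag means the second argument `y` trails the
#' first argument `x`. Cells with fewer than `min_valid_fraction` valid
#' overlapping frame pairs, or zero variance in either segment, are `NA`.
#'
#' @param x,y [channel_series()] of equal length and fps.
#' @param cfg a [sync_config()].
#' @return an object of class `crosscorr_matrix`: list with `values`
#'   (windows x lags), `lag_axis` (frames, `-L..L`), `window_starts`.
#' @export
windowed_cross_lagged_correlation <- function(x, y, cfg) {
  if (length(x) != length(y))
    stop_arg("series lengths differ: %d vs %d", length(x), length(y))
  if (x$fps != y$fps) stop_arg("series fps differ: %g vs %g", x$fps, y$fps)
  n <- length(x)
  W <- cfg$window_frames
  L <- cfg$max_lag_frames
  starts <- window_starts(n, cfg)
  if (length(starts) == 0L)
    stop_arg("series too short: need >= window + 2*max_lag = %d frames, got %d",
             W + 2L * L, n)
  lags <- seq.int(-L, L)
  all_valid <- all(x$valid) && all(y$valid)
  vals <- if (all_valid) {
    wclc_fast(x$values, y$values, starts, lags, W)
  } else {
    wclc_masked(x$values, y$values, x$valid & y_mask_ok(y), y$valid,
                starts, lags, W, cfg$min_valid_fraction)
  }
  structure(list(values = vals, lag_axis = lags, window_starts = starts),
            class = "crosscorr_matrix")
}

y_mask_ok <- function(y) rep(TRUE, length(y$values))

# cumulative-sum implementation: O(n) per lag, no per-window loops
wclc_fast <- function(xv, yv, starts, lags, W) {
  n <- length(xv)
  # global centering leaves window correlations unchanged but avoids the
  # catastrophic cancellation of two-pass moment formulas on offset signals
  xv <- xv - mean(xv)
  yv <- yv - mean(yv)
  csx <- c(0, cumsum(xv)); csx2 <- c(0, cumsum(xv^2))
  csy <- c(0, cumsum(yv)); csy2 <- c(0, cumsum(yv^2))
  sx <- csx[starts + W] - csx[starts]
  sx2 <- csx2[starts + W] - csx2[starts]
  out <- matrix(NA_real_, length(starts), length(lags))
  for (j in seq_along(lags)) {
    k <- lags[j]
    ys <- starts + k
    sy <- csy[ys + W] - csy[ys]
    sy2 <- csy2[ys + W] - csy2[ys]
    # cross products x[t] * y[t+k] accumulated over the aligned overlap
    if (k >= 0) {
      cp <- c(0, cumsum(xv[seq_len(n - k)] * yv[seq.int(1 + k, n)]))
      sxy <- cp[starts + W] - cp[starts]
    } else {
      m <- -k
      cp <- c(0, cumsum(xv[seq.int(1 + m, n)] * yv[seq_len(n - m)]))
      sxy <- cp[starts - m + W] - cp[starts - m]
    }
    num <- W * sxy - sx * sy
    dx <- W * sx2 - sx^2
    dy <- W * sy2 - sy^2
    den <- sqrt(pmax(dx, 0) * pmax(dy, 0))
    r <- ifelse(dx <= sqrt(.Machine$double.eps) * W * pmax(sx2, 1) |
                  dy <= sqrt(.Machine$double.eps) * W * pmax(sy2, 1) |
                  den == 0,
                NA_real_, num / den)
    out[, j] <- pmin(pmax(r, -1), 1)
  }
  out
}

wclc_masked <- function(xv, yv, xok, yok, starts, lags, W, min_frac) {
  out <- matrix(NA_real_, length(starts), length(lags))
  for (w in seq_along(starts)) {
    s <- starts[w]
    xi <- seq.int(s, s + W - 1L)
    for (j in seq_along(lags)) {
      yi <- xi + lags[j]
      ok <- xok[xi] & yok[yi]
      if (mean(ok) < min_frac || sum(ok) < 3L) next
      a <- xv[xi][ok]; b <- yv[yi][ok]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      out[w, j] <- min(max(stats::cor(a, b), -1), 1)
    }
  }
  out
}

#' Per-window peak synchrony profile
#'
#' Reduces a cross-correlation matrix to one value per window: the peak
#' correlation over the lag half matching the requested direction. With the
#' pipeline's sign convention (positive lag = `y` trails `x`), `"A_leads"`
#' scans nonnegative lags (the second series follows the first),
#' `"B_leads"` scans nonpositive lags, and `"pooled"` scans all lags. Lag 0
#' belongs to both halves: a simultaneous match is both leading and
#' following.
#'
#' @param m a `crosscorr_matrix`.
#' @param direction `"pooled"`, `"A_leads"` or `"B_leads"`.
#' @param peak_rule `"max_positive"` (default) or `"max_absolute"`.
#' @return an object of class `peak_profile`: list with `peak` (one value
#'   per window, `NA` where no cell is defined), `direction`,
#'   `window_starts`.
#' @export
peak_synchrony_profile <- function(m, direction = c("pooled", "A_leads",
                                                    "B_leads"),
                                   peak_rule = c("max_positive",
                                                 "max_absolute")) {
  direction <- match.arg(direction)
  peak_rule <- match.arg(peak_rule)
  keep <- switch(direction,
                 pooled = rep(TRUE, length(m$lag_axis)),
                 A_leads = m$lag_axis >= 0,
                 B_leads = m$lag_axis <= 0)
  sub <- m$values[, keep, drop = FALSE]
  peak <- apply(sub, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0L) return(NA_real_)
    if (peak_rule == "max_positive") max(r) else r[which.max(abs(r))]
  })
  structure(list(peak = as.numeric(peak), direction = direction,
                 window_starts = m$window_starts),
            class = "peak_profile")
}

#' The seven synchrony summary statistics
#'
#' Summarizes a per-window peak profile by mean, median, standard deviation
#' (sample, n-1), minimum, maximum, skewness (g1) and excess kurtosis (g2),
#' computed over non-missing windows. With fewer than two non-missing
#' windows all seven are `NA`; a constant profile has defined location
#' statistics and `sd = 0` but undefined (`NA`) shape moments.
#'
#' @param p a `peak_profile` or bare numeric vector.
#' @return a `sync_summary`: named numeric vector with elements `mean`,
#'   `median`, `sd`, `min`, `max`, `skewness`, `kurtosis`.
#' @export
summarize_profile <- function(p) {
  v <- if (inherits(p, "peak_profile")) p$peak else as.numeric(p)
  v <- v[!is.na(v)]
  if (length(v) < 2L) {
    out <- rep(NA_real_, 7L)
  } else {
    out <- c(mean(v), stats::median(v), stats::sd(v), min(v), max(v),
             sample_skewness(v), sample_kurtosis(v))
  }
  structure(stats::setNames(out, c("mean", "median", "sd", "min", "max",
                                   "skewness", "kurtosis")),
            class = "sync_summary")
}

na_summary <- function(reason = NULL) {
  out <- summarize_profile(numeric())
  attr(out, "reason") <- reason
  out
}

#' Following summary: how much one member trails their partner
#'
#' The degree to which `self` imitates (follows) `partner` in a channel:
#' the summary of the per-window peak correlations over the lags where
#' `self` trails `partner`. Defined on
#' `windowed_cross_lagged_correlation(partner, self)` restricted to
#' nonnegative lags, so swapping the two participants exchanges the two
#' members' summaries exactly.
#'
#' @param self,partner [ts_bundle()]s from the same task (or two
#'   [channel_series()] directly).
#' @param channel channel name, required when bundles are given.
#' @param cfg a [sync_config()].
#' @return a `sync_summary`; all-`NA` with a `reason` attribute when the
#'   channel is unusable.
#' @export
interpersonal_following_summary <- function(self, partner, channel = NULL,
                                            cfg) {
  sc <- pick_channel(self, channel)
  pc <- pick_channel(partner, channel)
  if (!sc$usable || !pc$usable)
    return(na_summary(reason = "channel unusable after preprocessing"))
  m <- windowed_cross_lagged_correlation(pc, sc, cfg)
  summarize_profile(peak_synchrony_profile(m, "A_leads", cfg$peak_rule))
}

pick_channel <- function(x, channel) {
  if (inherits(x, "channel_series")) return(x)
  if (inherits(x, "ts_bundle")) {
    if (is.null(channel)) stop_arg("`channel` is required with bundles")
    return(bundle_channel(x, channel))
  }
  stop_arg("expected a channel_series or ts_bundle")
}

#' Intrapersonal head-body coordination summary
#'
#' Pooled-direction peak synchrony between a participant's own
#' head-movement and body motion-energy series. The per-window peak is
#' taken over both argument orders' lag scans, making the summary exactly
#' symmetric in its two arguments.
#'
#' @param head,body [channel_series()] of the same participant and task.
#' @param cfg a [sync_config()].
#' @return a `sync_summary`.
#' @export
intrapersonal_summary <- function(head, body, cfg) {
  if (!head$usable || !body$usable)
    return(na_summary(reason = "channel unusable after preprocessing"))
  m1 <- windowed_cross_lagged_correlation(head, body, cfg)
  m2 <- windowed_cross_lagged_correlation(body, head, cfg)
  p1 <- peak_synchrony_profile(m1, "pooled", cfg$peak_rule)
  p2 <- peak_synchrony_profile(m2, "pooled", cfg$peak_rule)
  comb <- mapply(function(a, b) {
    if (is.na(a) && is.na(b)) return(NA_real_)
    if (cfg$peak_rule == "max_positive") max(a, b, na.rm = TRUE)
    else { v <- c(a, b); v <- v[!is.na(v)]; v[which.max(abs(v))] }
  }, p1$peak, p2$peak)
  summarize_profile(as.numeric(comb))
}

#' Pseudo-dyad surrogate baseline
#'
#' Null distribution of following-summary means obtained by pairing
#' participants who never actually interacted: random non-partner pairings
#' are each scored with [interpersonal_following_summary()], giving a
#' chance-level reference for observed synchrony.
#'
#' @param bundles list of [ts_bundle()] (one task, one channel of interest).
#' @param channel channel name.
#' @param cfg a [sync_config()].
#' @param n_pairings number of surrogate pairings, >= 1.
#' @param seed integer seed.
#' @param partner_map optional named character vector, participant id ->
#'   real partner id; real partners are never paired.
#' @param statistic which summary statistic to collect (default `"mean"`).
#' @return list with `values` (length `n_pairings`), `quantile` (function),
#'   and `pairings` (data frame of the surrogate pairs).
#' @export
pseudo_dyad_baseline <- function(bundles, channel, cfg, n_pairings, seed,
                                 partner_map = NULL, statistic = "mean") {
  n_pairings <- check_count(n_pairings, "n_pairings", min = 1L)
  if (length(bundles) < 2L) stop_arg("need at least 2 bundles")
  ids <- vapply(bundles, function(b) b$participant_id, character(1))
  names(bundles) <- ids
  withr::with_seed(seed, {
    pairs <- matrix(NA_character_, n_pairings, 2L)
    for (i in seq_len(n_pairings)) {
      repeat {
        pr <- sample(ids, 2L)
        real <- !is.null(partner_map) &&
          (identical(unname(partner_map[pr[1]]), pr[2]) ||
             identical(unname(partner_map[pr[2]]), pr[1]))
        if (!real) break
      }
      pairs[i, ] <- pr
    }
  })
  values <- vapply(seq_len(n_pairings), function(i) {
    s <- interpersonal_following_summary(bundles[[pairs[i, 1]]],
                                         bundles[[pairs[i, 2]]],
                                         channel, cfg)
    unname(s[statistic])
  }, numeric(1))
  list(values = values,
       quantile = function(p) stats::quantile(values, p, na.rm = TRUE,
                                              names = FALSE),
       pairings = data.frame(self = pairs[, 1], partner = pairs[, 2],
                             stringsAsFactors = FALSE))
}
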