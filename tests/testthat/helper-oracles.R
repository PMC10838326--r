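# Independent brute-force oracles used to check the vectorized
# implementations, plus small fixture builders.

# triple-loop windowed cross-lagged correlation (window x lag grid of
# plain cor() calls, full-overlap window placement)
naive_wclc <- function(xv, yv, W, L, step) {
  starts <- seq(L + 1, length(xv) - W - L + 1, by = step)
  vals <- matrix(NA_real_, length(starts), 2 * L + 1)
  for (w in seq_along(starts)) {
    s <- starts[w]
    for (j in seq_len(2 * L + 1)) {
      k <- j - L - 1
      a <- xv[s:(s + W - 1)]
      b <- yv[(s + k):(s + k + W - 1)]
      if (stats::sd(a) > 0 && stats::sd(b) > 0)
        vals[w, j] <- stats::cor(a, b)
    }
  }
  vals
}

# per-pixel double-loop motion energy for one ROI over a grayscale stack
naive_motion_energy <- function(frames, roi, threshold, normalize = TRUE) {
  rows <- (roi$y0 + 1):roi$y1
  cols <- (roi$x0 + 1):roi$x1
  e <- numeric(length(frames))
  for (t in 2:length(frames)) {
    s <- 0
    for (i in rows) for (j in cols) {
      d <- abs(frames[[t]][i, j] - frames[[t - 1]][i, j])
      if (d > threshold) s <- s + d
    }
    e[t] <- if (normalize) s / (length(rows) * length(cols)) else s
  }
  e
}

# naive per-window peak scan over a lag-subset of a cross-correlation matrix
naive_peak_scan <- function(values, lag_axis, direction, rule = "max_positive") {
  keep <- switch(direction,
                 pooled = rep(TRUE, length(lag_axis)),
                 A_leads = lag_axis >= 0,
                 B_leads = lag_axis <= 0)
  apply(values[, keep, drop = FALSE], 1, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) return(NA_real_)
    if (rule == "max_positive") max(r) else r[which.max(abs(r))]
  })
}

# a quick labeled feature matrix with a planted class shift on some columns
make_shifted_features <- function(labels, p = 6, shift = 0, seed = 1,
                                  shifted_cols = seq_len(min(5, p))) {
  withr::with_seed(seed, {
    ids <- names(labels$labels)
    X <- matrix(stats::rnorm(length(ids) * p), length(ids),
                dimnames = list(ids, paste0("f", seq_len(p))))
    pos <- labels$labels == levels(labels$labels)[1]
    X[pos, shifted_cols] <- X[pos, shifted_cols] + shift
    X
  })
}

default_labels <- function(n_mixed = 28, n_control = 16, seed = 2) {
  dyad_labels(generate_roster(n_mixed, n_control, seed = seed))
}
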