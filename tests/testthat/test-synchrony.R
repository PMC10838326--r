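cfg600 <- sync_config(window_frames = 90, step_frames = 10,
                      max_lag_frames = 30)

test_that("preprocessing gates on confidence, interpolates short gaps, flags heavy loss", {
  ch <- channel_series(sin(1:100 / 10), 30)
  expect_identical(preprocess_series(ch), ch)

  v <- rep(1, 11); v[6] <- 99
  raw <- channel_series(v, 30, valid = c(rep(TRUE, 5), FALSE, rep(TRUE, 5)))
  raw$values[6] <- NA
  out <- preprocess_series(raw)
  expect_equal(out$values[6], (raw$values[5] + raw$values[7]) / 2)
  expect_true(out$valid[6])
  expect_true(out$usable)

  # confidence below threshold invalidates, long gaps stay invalid
  conf <- channel_series(c(rep(1, 40), rep(0.2, 20), rep(1, 40)), 30)
  raw2 <- channel_series(rnorm(100), 30)
  out2 <- preprocess_series(raw2, conf,
                            preprocess_config(max_gap_frames = 10))
  expect_true(all(!out2$valid[41:60]))
  expect_true(all(is.na(out2$values[41:60])))

  # 15% invalid against a 10% exclusion threshold -> unusable (even though
  # the gaps themselves are repairable)
  valid <- rep(TRUE, 100); valid[c(11:17, 31:38)] <- FALSE
  raw3 <- channel_series(rnorm(100), 30, valid = valid)
  out3 <- preprocess_series(raw3, config = preprocess_config(
    max_gap_frames = 10, exclusion_threshold = 0.1))
  expect_false(out3$usable)
})

test_that("cross-lagged correlation matches the triple-loop oracle to 1e-10", {
  withr::with_seed(101, {
    for (i in 1:10) {
      xv <- rnorm(600); yv <- rnorm(600)
      m <- windowed_cross_lagged_correlation(
        channel_series(xv, 30), channel_series(yv, 30), cfg600)
      o <- naive_wclc(xv, yv, 90, 30, 10)
      expect_lt(max(abs(m$values - o)), 1e-10)
      expect_true(all(abs(m$values) <= 1, na.rm = TRUE))
    }
  })
})

test_that("cross-lagged correlation honors its sign convention and degenerate cases", {
  withr::with_seed(5, xv <- rnorm(600))
  x <- channel_series(xv, 30)
  m <- windowed_cross_lagged_correlation(x, x, cfg600)
  expect_true(all(abs(m$values[, m$lag_axis == 0] - 1) < 1e-12))

  k0 <- 7  # y trails x by 7 frames -> peak at +7 (positive lag = y trails x)
  y <- channel_series(c(rep(0, k0), xv)[1:600], 30)
  m2 <- windowed_cross_lagged_correlation(x, y, cfg600)
  peaks <- m2$lag_axis[apply(m2$values, 1, which.max)]
  expect_true(all(peaks == k0))

  const <- channel_series(rep(3, 600), 30)
  m3 <- windowed_cross_lagged_correlation(x, const, cfg600)
  expect_true(all(is.na(m3$values)))

  expect_error(windowed_cross_lagged_correlation(
    x, channel_series(rnorm(500), 30), cfg600), "lengths differ")
  expect_error(windowed_cross_lagged_correlation(
    channel_series(rnorm(100), 30), channel_series(rnorm(100), 30), cfg600),
    "too short")
})

test_that("window count follows the full-overlap arithmetic", {
  for (Tn in c(300, 301, 437, 600)) {
    for (step in c(1, 7, 10)) {
      cfg <- sync_config(90, step, 30)
      x <- channel_series(rnorm(Tn), 30)
      m <- windowed_cross_lagged_correlation(x, x, cfg)
      expect_equal(nrow(m$values), floor((Tn - 90 - 60) / step) + 1)
      # enumeration: every admissible start is on the grid
      starts <- m$window_starts
      expect_true(all(starts + 90 + 30 - 1 <= Tn + 30))
      expect_equal(starts[1], 31)
    }
  }
})

test_that("reversing both series mirrors the lag axis", {
  # sized so the reversed window grid lands on itself
  cfg <- sync_config(90, 10, 30)
  withr::with_seed(33, { xv <- rnorm(610); yv <- rnorm(610) })
  m <- windowed_cross_lagged_correlation(channel_series(xv, 30),
                                         channel_series(yv, 30), cfg)
  mr <- windowed_cross_lagged_correlation(channel_series(rev(xv), 30),
                                          channel_series(rev(yv), 30), cfg)
  expect_equal(mr$values,
               m$values[rev(seq_len(nrow(m$values))),
                        rev(seq_len(ncol(m$values)))],
               tolerance = 1e-12)
})

test_that("masked windows drop below the valid-overlap floor", {
  withr::with_seed(12, { xv <- rnorm(300); yv <- rnorm(300) })
  valid <- rep(TRUE, 300); valid[100:160] <- FALSE
  x <- channel_series(xv, 30, valid = valid)
  y <- channel_series(yv, 30)
  cfg <- sync_config(90, 10, 30, min_valid_fraction = 0.9)
  m <- windowed_cross_lagged_correlation(x, y, cfg)
  # windows fully inside the invalid block are missing; clean windows are not
  expect_true(anyNA(m$values))
  clean <- m$window_starts > 160  # x-window clear of the invalid block
  expect_true(any(clean))
  expect_true(all(!is.na(m$values[clean, ])))
})

test_that("peak profiles equal the naive per-window scan", {
  withr::with_seed(21, {
    vals <- matrix(rnorm(40 * 13), 40, 13)
    vals[sample(length(vals), 30)] <- NA
  })
  m <- structure(list(values = vals, lag_axis = -6:6,
                      window_starts = seq_len(40)),
                 class = "crosscorr_matrix")
  for (dir in c("pooled", "A_leads", "B_leads")) {
    for (rule in c("max_positive", "max_absolute")) {
      p <- peak_synchrony_profile(m, dir, rule)
      expect_equal(p$peak, unname(naive_peak_scan(vals, -6:6, dir, rule)))
    }
  }
  pooled <- peak_synchrony_profile(m, "pooled")$peak
  a <- peak_synchrony_profile(m, "A_leads")$peak
  b <- peak_synchrony_profile(m, "B_leads")$peak
  expect_true(all(pooled >= a, na.rm = TRUE))
  expect_true(all(pooled >= b, na.rm = TRUE))

  inc <- structure(list(values = matrix(seq(-0.6, 0.6, length.out = 13),
                                        3, 13, byrow = TRUE),
                        lag_axis = -6:6, window_starts = 1:3),
                   class = "crosscorr_matrix")
  expect_equal(peak_synchrony_profile(inc, "A_leads")$peak, rep(0.6, 3))
})

test_that("the seven summary statistics behave as documented", {
  s <- summarize_profile(c(0.1, 0.2, 0.3))
  expect_equal(unname(s[c("mean", "median", "min", "max", "sd")]),
               c(0.2, 0.2, 0.1, 0.3, 0.1))

  const <- summarize_profile(rep(0.4, 10))
  expect_equal(unname(const["mean"]), 0.4)
  expect_equal(unname(const["sd"]), 0)
  expect_true(is.na(const["skewness"]) && is.na(const["kurtosis"]))

  sym <- summarize_profile(c(-2, -1, 0, 1, 2))
  expect_lt(abs(sym[["skewness"]]), 1e-12)

  expect_true(all(is.na(summarize_profile(c(0.5, NA, NA)))))

  # cross-check the shape moments against an established implementation
  withr::with_seed(3, v <- rnorm(200))
  expect_equal(summarize_profile(v)[["skewness"]],
               e1071::skewness(v, type = 1))
  expect_equal(summarize_profile(v)[["kurtosis"]],
               e1071::kurtosis(v, type = 1))
})

test_that("following summaries capture direction and swap with roles", {
  withr::with_seed(44, base <- as.numeric(stats::filter(
    rnorm(620, sd = sqrt(1 - 0.9^2)), 0.9, "recursive")))
  partner <- channel_series(base[21:620], 30, name = "AU01_r")
  self <- channel_series(base[1:600], 30, name = "AU01_r")  # trails by 20
  cfg <- sync_config(90, 10, 30)
  fol_self <- interpersonal_following_summary(self, partner, cfg = cfg)
  fol_partner <- interpersonal_following_summary(partner, self, cfg = cfg)
  expect_gt(fol_self[["mean"]], 0.99)
  expect_gt(fol_self[["mean"]], fol_partner[["mean"]] + 0.05)

  # role swap: each member's summary is defined on the partner-first matrix,
  # so the pair (f1, f2) is exchanged exactly when the members are swapped
  withr::with_seed(9, { a <- rnorm(600); b <- rnorm(600) })
  ca <- channel_series(a, 30); cb <- channel_series(b, 30)
  f1 <- interpersonal_following_summary(ca, cb, cfg = cfg)
  f2 <- interpersonal_following_summary(cb, ca, cfg = cfg)
  m1 <- windowed_cross_lagged_correlation(cb, ca, cfg)
  m2 <- windowed_cross_lagged_correlation(ca, cb, cfg)
  expect_equal(unname(f1["mean"]),
               mean(naive_peak_scan(m1$values, m1$lag_axis, "A_leads")))
  expect_equal(unname(f2["mean"]),
               mean(naive_peak_scan(m2$values, m2$lag_axis, "A_leads")))
  expect_false(isTRUE(all.equal(f1, f2)))

  bad <- channel_series(a, 30, usable = FALSE)
  miss <- interpersonal_following_summary(bad, cb, cfg = cfg)
  expect_true(all(is.na(miss)))
  expect_match(attr(miss, "reason"), "unusable")
})

test_that("white-noise pairs show no systematic leader or follower", {
  cfg <- sync_config(60, 20, 15)
  d <- replicate(60, {
    a <- channel_series(rnorm(300), 30)
    b <- channel_series(rnorm(300), 30)
    interpersonal_following_summary(a, b, cfg = cfg)[["mean"]] -
      interpersonal_following_summary(b, a, cfg = cfg)[["mean"]]
  })
  expect_gt(stats::t.test(d)$p.value, 0.01)
})

test_that("intrapersonal coordination is symmetric and tracks coupling", {
  cfg <- sync_config(90, 30, 30)
  withr::with_seed(55, base <- as.numeric(stats::filter(
    rnorm(600, sd = 0.3), 0.9, "recursive")))
  head <- channel_series(base, 30, name = "head_movement")
  body <- channel_series(2.5 * base + 1, 30, name = "body")
  s <- intrapersonal_summary(head, body, cfg)
  expect_gt(s[["mean"]], 0.999)
  expect_identical(unclass(intrapersonal_summary(body, head, cfg)),
                   unclass(s))

  withr::with_seed(56, {
    h2 <- channel_series(rnorm(600), 30)
    b2 <- channel_series(rnorm(600), 30)
  })
  expect_identical(unclass(intrapersonal_summary(h2, b2, cfg)),
                   unclass(intrapersonal_summary(b2, h2, cfg)))
})

test_that("pseudo-dyad baselines separate coupled pairs from chance", {
  cfg <- sync_config(60, 20, 15)
  prof <- coupling_profile(c(face = 0.9, head = 0.9, body = 0.9),
                           noise_sd = 0.05)
  bundles <- list(); partner_map <- character()
  for (d in 1:6) {
    pr <- simulate_dyad_timeseries(prof, duration = 12, fps = 30,
                                   n_au_channels = 1, seed = 600 + d,
                                   ids = sprintf("P%02d", c(2 * d - 1, 2 * d)))
    bundles[[2 * d - 1]] <- pr$a
    bundles[[2 * d]] <- pr$b
    partner_map[pr$a$participant_id] <- pr$b$participant_id
    partner_map[pr$b$participant_id] <- pr$a$participant_id
  }
  null <- pseudo_dyad_baseline(bundles, "AU01_r", cfg, n_pairings = 40,
                               seed = 77, partner_map = partner_map)
  expect_length(null$values, 40)
  # surrogates never pair real partners
  for (i in seq_len(nrow(null$pairings)))
    expect_false(identical(unname(partner_map[null$pairings$self[i]]),
                           null$pairings$partner[i]))
  # the real coupled pairs sit above the null's 97.5th percentile
  real <- vapply(1:6, function(d)
    interpersonal_following_summary(bundles[[2 * d]], bundles[[2 * d - 1]],
                                    "AU01_r", cfg)[["mean"]], numeric(1))
  expect_gt(mean(real), null$quantile(0.975))
  expect_identical(pseudo_dyad_baseline(bundles, "AU01_r", cfg, 10, seed = 3,
                                        partner_map = partner_map)$pairings,
                   pseudo_dyad_baseline(bundles, "AU01_r", cfg, 10, seed = 3,
                                        partner_map = partner_map)$pairings)
  expect_error(pseudo_dyad_baseline(bundles, "AU01_r", cfg, 0, seed = 1),
               "n_pairings")
})
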