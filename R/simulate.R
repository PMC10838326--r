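#' Coupling profile for a simulated dyad member
#'
#' Parameterizes how strongly and at what delay one member of a simulated
#' dyad adapts to (follows) their partner, per channel group. The generative
#' model per channel is a lagged feedback system on latent signals: the
#' member's latent at frame t is
#' `coupling * partner_latent[t - lag] + (1 - coupling) * own AR(1)[t]`,
#' plus Gaussian measurement noise, then mapped to the channel's observation
#' scale (AU intensities clipped to \[0, 5\], motion energy clipped at 0).
#' With coupling in both directions the two members share genuine joint
#' dynamics; with one-sided coupling the follower is a damped, lag-shifted
#' copy of the partner.
#'
#' @param coupling_strength named numeric vector in \[0, 1\] with entries
#'   `face`, `head`, `body`: how much this member follows the partner in each
#'   channel group. A scalar is recycled to all three groups.
#' @param coupling_lag delay in seconds (>= 0) at which following occurs;
#'   `coupling_lag * fps` must be a whole number of frames at simulation time.
#' @param base_ar autoregressive coefficient of the latent AR(1) processes,
#'   in (-1, 1). Default 0.95 gives smooth behavior-like drift at 30 fps.
#' @param noise_sd standard deviation (signal units, >= 0) of the additive
#'   measurement noise on this member's latents.
#' @param intrapersonal_coupling in \[0, 1\]: how much the member's body
#'   latent mixes with their own head latent (drives head-body coordination).
#' @return an object of class `coupling_profile`.
#' @export
coupling_profile <- function(coupling_strength = 0.6, coupling_lag = 0.5,
                             base_ar = 0.95, noise_sd = 0.1,
                             intrapersonal_coupling = 0.3) {
  if (length(coupling_strength) == 1L && is.null(names(coupling_strength)))
    coupling_strength <- c(face = coupling_strength, head = coupling_strength,
                           body = coupling_strength)
  if (!all(c("face", "head", "body") %in% names(coupling_strength)))
    stop_arg("`coupling_strength` needs entries face, head, body (or a scalar)")
  if (any(coupling_strength < 0 | coupling_strength > 1))
    stop_arg("`coupling_strength` must lie in [0, 1]")
  if (coupling_lag < 0) stop_arg("`coupling_lag` must be >= 0 seconds")
  if (abs(base_ar) >= 1) stop_arg("`base_ar` must lie in (-1, 1)")
  if (noise_sd < 0) stop_arg("`noise_sd` must be >= 0")
  check_fraction(intrapersonal_coupling, "intrapersonal_coupling")
  structure(list(coupling_strength = coupling_strength[c("face", "head", "body")],
                 coupling_lag = coupling_lag, base_ar = base_ar,
                 noise_sd = noise_sd,
                 intrapersonal_coupling = intrapersonal_coupling),
            class = "coupling_profile")
}

#' Default retained facial action-unit channels
#'
#' The twelve AU intensity channels kept after missingness screening, in
#' OpenFace column naming (`AUxx_r`).
#' @return character vector of 12 channel names.
#' @export
default_au_set <- function() {
  sprintf("AU%02d_r", c(1, 4, 6, 7, 10, 12, 15, 17, 20, 25, 26, 45))
}

#' The two conversation tasks
#' @return character vector `c("hobbies", "mealplanning")`.
#' @export
task_names <- function() c("hobbies", "mealplanning")

# AR(1) innovations scaled so the stationary variance is 1
ar1 <- function(n, phi) {
  as.numeric(stats::filter(stats::rnorm(n, sd = sqrt(1 - phi^2)), phi,
                           method = "recursive",
                           init = stats::rnorm(1)))
}

# Solve the coupled lagged system for one channel:
#   a[t] = cA * b[t - lagA] + (1 - cA) * baseA[t]   for t > lagA
#   b[t] = cB * a[t - lagB] + (1 - cB) * baseB[t]   for t > lagB
# with own-base initial segments. Unidirectional cases reduce to a single
# vectorized shift (cB = 1 with zero noise gives b as an exact lagged copy
# of a); the mutual case is advanced in chunks of the shorter lag, inside
# which every cross-reference is already final. A zero-lag coupled
# direction uses the partner's base process to avoid an algebraic loop.
coupled_pair <- function(baseA, baseB, cA, cB, lagA, lagB) {
  nt <- length(baseA)
  mix_now <- function(base, partner_base, cs)
    cs * partner_base + (1 - cs) * base
  follow <- function(base, src, cs, lg) {
    out <- base
    idx <- (lg + 1):nt
    out[idx] <- cs * src[idx - lg] + (1 - cs) * base[idx]
    out
  }
  if (cA == 0 && cB == 0) return(list(a = baseA, b = baseB))
  if (cA == 0) {
    b <- if (lagB == 0) mix_now(baseB, baseA, cB)
         else follow(baseB, baseA, cB, lagB)
    return(list(a = baseA, b = b))
  }
  if (cB == 0) {
    a <- if (lagA == 0) mix_now(baseA, baseB, cA)
         else follow(baseA, baseB, cA, lagA)
    return(list(a = a, b = baseB))
  }
  if (lagA == 0 || lagB == 0) {
    a <- if (lagA == 0) mix_now(baseA, baseB, cA)
         else follow(baseA, baseB, cA, lagA)
    b <- if (lagB == 0) mix_now(baseB, baseA, cB)
         else follow(baseB, baseA, cB, lagB)
    return(list(a = a, b = b))
  }
  a <- baseA; b <- baseB
  m <- min(lagA, lagB)
  s <- 1L
  while (s <= nt) {
    idx <- s:min(s + m - 1L, nt)
    ia <- idx[idx > lagA]
    if (length(ia)) a[ia] <- cA * b[ia - lagA] + (1 - cA) * baseA[ia]
    ib <- idx[idx > lagB]
    if (length(ib)) b[ib] <- cB * a[ib - lagB] + (1 - cB) * baseB[ib]
    s <- s + m
  }
  list(a = a, b = b)
}

# observation maps, applied identically to both members so that a noise-free
# unit-coupling member is an exactly lag-shifted copy of the partner
obs_au <- function(z) pmin(pmax(2.5 + 0.8 * z, 0), 5)
obs_pose <- function(z) 0.2 * z
obs_body <- function(z) pmax(1 + 0.5 * z, 0)

#' Simulate one dyad's behavioral time series
#'
#' Generates paired `ts_bundle`s for the two members of a dyad: AU intensity
#' channels (face group), three head-pose rotation channels (head group) and
#' a body motion-energy channel (body group). Member B follows member A
#' according to `profile`; member A optionally follows B according to
#' `profile_a` (default: no back-coupling, i.e. A is autonomous).
#'
#' @param profile a [coupling_profile()] governing B's following of A.
#' @param duration recording length in seconds (> 0); default 600 (two
#'   ten-minute conversation tasks are simulated by calling this twice).
#' @param fps frames per second (> 0); default 30.
#' @param n_au_channels number of AU channels (default 12, named via
#'   [default_au_set()]).
#' @param seed integer seed; output is deterministic given the seed.
#' @param profile_a optional [coupling_profile()] for A following B.
#' @param task task label stored in the bundles.
#' @param ids character vector of length 2: participant ids for A and B.
#' @return list with elements `a` and `b`, each a [ts_bundle()].
#' @export
simulate_dyad_timeseries <- function(profile, duration = 600, fps = 30,
                                     n_au_channels = 12, seed,
                                     profile_a = NULL,
                                     task = "hobbies",
                                     ids = c("A", "B")) {
  if (duration <= 0) stop_arg("`duration` must be > 0 seconds")
  if (fps <= 0) stop_arg("`fps` must be > 0")
  n_au_channels <- check_count(n_au_channels, "n_au_channels", min = 1L)
  if (is.null(profile_a))
    profile_a <- coupling_profile(0, profile$coupling_lag, profile$base_ar,
                                  profile$noise_sd,
                                  profile$intrapersonal_coupling)
  lag_f <- profile$coupling_lag * fps
  if (abs(lag_f - round(lag_f)) > 1e-9)
    stop_arg("coupling_lag (%g s) x fps (%g) is not a whole number of frames",
             profile$coupling_lag, fps)
  lag_f <- as.integer(round(lag_f))
  lag_fa <- profile_a$coupling_lag * fps
  if (abs(lag_fa - round(lag_fa)) > 1e-9)
    stop_arg("profile_a coupling_lag x fps is not a whole number of frames")
  lag_fa <- as.integer(round(lag_fa))

  n <- as.integer(round(duration * fps))
  burn <- max(lag_f, lag_fa)
  nt <- n + burn
  au_names <- if (n_au_channels == 12L) default_au_set() else
    sprintf("AU%02d_r", seq_len(n_au_channels))
  chan_group <- c(stats::setNames(rep("face", n_au_channels), au_names),
                  pose_Rx = "head", pose_Ry = "head", pose_Rz = "head",
                  body = "body")

  withr::with_seed(seed, {
    la <- lapply(chan_group, function(g) ar1(nt, profile$base_ar))
    lb <- lapply(chan_group, function(g) ar1(nt, profile$base_ar))
    # intrapersonal head-body mixing within each member
    mix_intra <- function(lat, w) {
      if (w > 0) {
        hm <- (lat$pose_Rx + lat$pose_Ry + lat$pose_Rz) / sqrt(3)
        lat$body <- w * hm + (1 - w) * lat$body
      }
      lat
    }
    la <- mix_intra(la, profile_a$intrapersonal_coupling)
    lb <- mix_intra(lb, profile$intrapersonal_coupling)

    # lagged feedback recursion: each member's realized signal couples to
    # the partner's realized signal `lag` frames earlier, so mutual coupling
    # produces genuinely shared dynamics (not two mirrored copies)
    za <- la; zb <- lb
    cA_all <- profile_a$coupling_strength
    cB_all <- profile$coupling_strength
    for (nm in names(chan_group)) {
      cA <- cA_all[[chan_group[[nm]]]]
      cB <- cB_all[[chan_group[[nm]]]]
      ab <- coupled_pair(la[[nm]], lb[[nm]], cA, cB, lag_fa, lag_f)
      za[[nm]] <- ab$a
      zb[[nm]] <- ab$b
    }
    add_noise <- function(lat, sdv) {
      if (sdv > 0) lapply(lat, function(z)
        z + stats::rnorm(length(z), sd = sdv)) else lat
    }
    za <- add_noise(za, profile_a$noise_sd)
    zb <- add_noise(zb, profile$noise_sd)

    observe <- function(lat, nm) {
      z <- lat[[nm]][(burn + 1):nt]
      switch(chan_group[[nm]],
             face = obs_au(z), head = obs_pose(z), body = obs_body(z))
    }
    make_bundle <- function(lat, id) {
      chans <- lapply(names(chan_group), function(nm)
        channel_series(observe(lat, nm), fps = fps, name = nm))
      names(chans) <- names(chan_group)
      ts_bundle(id, task, chans)
    }
    list(a = make_bundle(za, ids[1]), b = make_bundle(zb, ids[2]))
  })
}

#' Draw per-member coupling profiles for a whole roster
#'
#' Encodes the study contrast the classifier is meant to detect: members of
#' control (TD-TD) dyads follow their partner with coupling centered on 0.6
#' in both directions; in mixed (ASD-TD) dyads the TD member's coupling is
#' centered on 0.6 but the ASD member's on 0.2, and mixed-dyad couplings are
#' drawn with doubled spread (elevated variability of adaptation). Couplings
#' are truncated to \[0, 1\].
#'
#' @param roster a finalized `dyad_roster`.
#' @param seed integer seed.
#' @param mean_td,mean_asd coupling means for TD and ASD members (defaults
#'   0.6 / 0.2).
#' @param sd_control,sd_mixed coupling spreads for control and mixed dyads
#'   (defaults 0.1 / 0.2).
#' @param coupling_lag,base_ar,noise_sd,intrapersonal_coupling passed to
#'   [coupling_profile()].
#' @return named list, participant id -> `coupling_profile`.
#' @export
dyad_coupling_profiles <- function(roster, seed,
                                   mean_td = 0.6, mean_asd = 0.2,
                                   sd_control = 0.1, sd_mixed = 0.2,
                                   coupling_lag = 0.5, base_ar = 0.95,
                                   noise_sd = 0.1,
                                   intrapersonal_coupling = 0.3) {
  act <- active_roster(roster)
  tp <- dyad_types(roster)
  withr::with_seed(seed, {
    profs <- lapply(seq_len(nrow(act)), function(i) {
      mixed <- tp[[act$dyad_id[i]]] == "mixed"
      mu <- if (mixed && act$diagnosis[i] == "ASD") mean_asd else mean_td
      sdv <- if (mixed) sd_mixed else sd_control
      cs <- pmin(pmax(stats::rnorm(3, mu, sdv), 0), 1)
      coupling_profile(stats::setNames(cs, c("face", "head", "body")),
                       coupling_lag, base_ar, noise_sd,
                       intrapersonal_coupling)
    })
    names(profs) <- act$participant_id
    profs
  })
}

#' Simulate behavioral time series for every dyad and task of a roster
#'
#' @param roster a finalized `dyad_roster`.
#' @param seed integer seed.
#' @param duration,fps,n_au_channels as in [simulate_dyad_timeseries()].
#' @param profiles per-participant coupling profiles; default drawn by
#'   [dyad_coupling_profiles()] from the same seed.
#' @param tasks task labels; default both conversation tasks.
#' @return nested list: `bundles[[participant_id]][[task]]` is a
#'   [ts_bundle()].
#' @export
simulate_study <- function(roster, seed, duration = 600, fps = 30,
                           n_au_channels = 12, profiles = NULL,
                           tasks = task_names()) {
  act <- active_roster(roster)
  if (is.null(profiles))
    profiles <- dyad_coupling_profiles(roster, seed = seed + 1L)
  bundles <- list()
  dyads <- unique(act$dyad_id)
  for (di in seq_along(dyads)) {
    members <- act$participant_id[act$dyad_id == dyads[di]]
    for (ti in seq_along(tasks)) {
      pair <- simulate_dyad_timeseries(
        profile = profiles[[members[2]]], duration = duration, fps = fps,
        n_au_channels = n_au_channels,
        seed = seed + 1000L * di + ti,
        profile_a = profiles[[members[1]]],
        task = tasks[ti], ids = members)
      bundles[[members[1]]][[tasks[ti]]] <- pair$a
      bundles[[members[2]]][[tasks[ti]]] <- pair$b
    }
  }
  bundles
}

#' Render a synthetic frame stack encoding a motion series
#'
#' Produces grayscale frames in which the pixels of `roi` all change by the
#' same amount between consecutive frames, so that motion-energy analysis of
#' the stack recovers the input series up to a documented monotone scaling:
#' a zero series value maps to zero pixel change, and positive values map
#' affinely into `[min_change, max_change]` (strictly increasing). Pixels
#' outside the ROI are constant.
#'
#' @param body_series numeric vector or [channel_series()] of nonnegative
#'   motion values.
#' @param roi an [roi_spec()]; must fit inside `frame_shape`.
#' @param frame_shape integer vector `c(height, width)` in pixels.
#' @param seed integer seed (sets the ROI's starting gray level).
#' @param min_change,max_change pixel-change range for positive series
#'   values; `min_change` should exceed the motion-energy noise threshold in
#'   use downstream.
#' @param background gray level of non-ROI pixels.
#' @return list of `height x width` numeric matrices, one per frame
#'   (`length(body_series)` frames).
#' @export
render_motion_frames <- function(body_series, roi, frame_shape = c(48, 64),
                                 seed = 1, min_change = 12, max_change = 120,
                                 background = 30) {
  if (max_change <= min_change || max_change > 127)
    stop_arg("need min_change < max_change <= 127 so the gray level can always step away from the nearer boundary")
  if (inherits(body_series, "channel_series")) body_series <- body_series$values
  if (any(body_series < 0)) stop_arg("`body_series` must be nonnegative")
  h <- frame_shape[1]; w <- frame_shape[2]
  if (roi$y1 > h || roi$x1 > w)
    stop_arg("roi [%d,%d)x[%d,%d) exceeds frame shape %dx%d",
             roi$x0, roi$x1, roi$y0, roi$y1, h, w)
  n <- length(body_series)
  mx <- max(body_series)
  changes <- numeric(n)
  pos <- body_series > 0
  if (mx > 0)
    changes[pos] <- min_change +
      (max_change - min_change) * body_series[pos] / mx
  rows <- (roi$y0 + 1):roi$y1
  cols <- (roi$x0 + 1):roi$x1
  base <- matrix(background, h, w)
  withr::with_seed(seed, v <- stats::runif(1, 60, 120))
  frames <- vector("list", n)
  f <- base; f[rows, cols] <- v
  frames[[1]] <- f
  for (t in seq_len(n)[-1]) {
    # step the uniform ROI level toward the farther boundary of [0, 255];
    # with max_change <= 127 the level always stays in range
    v <- if (v < 127.5) v + changes[t] else v - changes[t]
    f <- base; f[rows, cols] <- v
    frames[[t]] <- f
  }
  frames
}
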