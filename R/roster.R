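#' Generate a dyad roster
#'
#' Builds a roster of dyads of two types: "mixed" dyads pair one autistic
#' (ASD) with one non-autistic (TD) participant; "control" dyads pair two TD
#' participants. Sex, age and IQ covariates are drawn per diagnosis group
#' from configurable distributions via [generate_cohort_covariates()].
#'
#' @param n_mixed number of ASD-TD dyads.
#' @param n_control number of TD-TD dyads.
#' @param seed integer seed; the roster is deterministic given the seed.
#' @param covariates logical; draw covariates (default `TRUE`).
#' @param config covariate distribution config, see
#'   [cohort_covariate_config()].
#' @return a `dyad_roster`: a data frame of participant records (columns
#'   `participant_id`, `dyad_id`, `diagnosis`, `sex`, `age`, `iq_crystalline`,
#'   `iq_nonverbal`, `excluded`, `exclusion_reason`) with a `dyad_type`
#'   attribute mapping dyad id to `"mixed"`/`"control"`.
#' @export
generate_roster <- function(n_mixed, n_control, seed,
                            covariates = TRUE,
                            config = cohort_covariate_config()) {
  n_mixed <- check_count(n_mixed, "n_mixed")
  n_control <- check_count(n_control, "n_control")
  n_dyads <- n_mixed + n_control
  if (n_dyads == 0L) {
    roster <- empty_roster()
    return(roster)
  }
  dyad_id <- sprintf("D%03d", seq_len(n_dyads))
  dyad_type <- c(rep("mixed", n_mixed), rep("control", n_control))
  participants <- data.frame(
    participant_id = sprintf("P%03d", seq_len(2L * n_dyads)),
    dyad_id = rep(dyad_id, each = 2L),
    diagnosis = as.vector(vapply(dyad_type, function(tp) {
      if (tp == "mixed") c("ASD", "TD") else c("TD", "TD")
    }, character(2))),
    stringsAsFactors = FALSE
  )
  participants$sex <- NA_character_
  participants$age <- NA_real_
  participants$iq_crystalline <- NA_real_
  participants$iq_nonverbal <- NA_real_
  participants$excluded <- FALSE
  participants$exclusion_reason <- NA_character_
  roster <- new_roster(participants, stats::setNames(dyad_type, dyad_id))
  if (covariates) roster <- generate_cohort_covariates(roster, config, seed)
  roster
}

new_roster <- function(participants, dyad_type) {
  structure(participants, dyad_type = dyad_type,
            class = c("dyad_roster", "data.frame"))
}

empty_roster <- function() {
  new_roster(
    data.frame(participant_id = character(), dyad_id = character(),
               diagnosis = character(), sex = character(), age = numeric(),
               iq_crystalline = numeric(), iq_nonverbal = numeric(),
               excluded = logical(), exclusion_reason = character(),
               stringsAsFactors = FALSE),
    stats::setNames(character(), character()))
}

#' @export
print.dyad_roster <- function(x, ...) {
  act <- active_roster(x)
  tp <- dyad_types(x)
  cat(sprintf("<dyad_roster> %d participants (%d active) in %d dyads (%d mixed, %d control)\n",
              nrow(x), nrow(act), length(unique(act$dyad_id)),
              sum(tp == "mixed"), sum(tp == "control")))
  NextMethod()
}

#' Dyad-type map of the active dyads in a roster
#'
#' @param roster a `dyad_roster`.
#' @return named character vector, dyad id -> `"mixed"` or `"control"`,
#'   restricted to dyads with non-excluded members.
#' @export
dyad_types <- function(roster) {
  tp <- attr(roster, "dyad_type")
  act <- unique(roster$dyad_id[!roster$excluded])
  tp[names(tp) %in% act]
}

#' Active (non-excluded) participants of a roster
#' @param roster a `dyad_roster`.
#' @return the roster restricted to non-excluded rows.
#' @export
active_roster <- function(roster) {
  new_roster(roster[!roster$excluded, , drop = FALSE],
             attr(roster, "dyad_type"))
}

#' Apply participant exclusions with partner propagation
#'
#' Because the unit of analysis is the dyad, excluding one participant forces
#' exclusion of their interaction partner (reason `partner_excluded`). The
#' finalized roster therefore only ever contains complete dyads.
#'
#' @param roster a `dyad_roster`.
#' @param exclusion_events data frame with columns `participant_id` and
#'   `reason` (one of `unverified_diagnosis`, `tracking_loss`, `technical`),
#'   or a named character vector `participant_id = reason`.
#' @return the roster with `excluded`/`exclusion_reason` filled in.
#' @export
apply_exclusions <- function(roster, exclusion_events) {
  if (is.character(exclusion_events)) {
    exclusion_events <- data.frame(participant_id = names(exclusion_events),
                                   reason = unname(exclusion_events),
                                   stringsAsFactors = FALSE)
  }
  if (nrow(exclusion_events) == 0L) return(roster)
  unknown <- setdiff(exclusion_events$participant_id, roster$participant_id)
  if (length(unknown))
    stop_arg("unknown participant id(s) in exclusion events: %s",
             paste(unknown, collapse = ", "))
  allowed <- c("unverified_diagnosis", "tracking_loss", "technical",
               "partner_excluded")
  bad <- setdiff(exclusion_events$reason, allowed)
  if (length(bad))
    stop_arg("unknown exclusion reason(s): %s", paste(bad, collapse = ", "))

  idx <- match(exclusion_events$participant_id, roster$participant_id)
  roster$excluded[idx] <- TRUE
  roster$exclusion_reason[idx] <- exclusion_events$reason
  # partner propagation: a dyad with one excluded member loses the other too
  for (d in unique(roster$dyad_id[idx])) {
    members <- which(roster$dyad_id == d)
    orphan <- members[!roster$excluded[members]]
    if (length(orphan)) {
      roster$excluded[orphan] <- TRUE
      roster$exclusion_reason[orphan] <- "partner_excluded"
    }
  }
  roster
}

#' Covariate distribution configuration for the synthetic cohort
#'
#' Per-diagnosis-group normal distributions for age and the two IQ measures
#' and a Bernoulli rate for sex. Defaults match a matched adult cohort:
#' ASD age 37.2 (13.1), TD 31.5 (10.8); crystalline IQ ~114 (17) in both
#' groups; non-verbal IQ 119.8 (23.4) vs 117.0 (17.4); female proportion
#' 18/28 in ASD and 26/60 in TD.
#'
#' @param age,iq_crystalline,iq_nonverbal lists with numeric `mean` and `sd`
#'   vectors named `ASD`/`TD`.
#' @param p_female named numeric vector of female probabilities per group.
#' @return a list config consumed by [generate_cohort_covariates()].
#' @export
cohort_covariate_config <- function(
    age = list(mean = c(ASD = 37.18, TD = 31.48),
               sd = c(ASD = 13.14, TD = 10.78)),
    iq_crystalline = list(mean = c(ASD = 113.68, TD = 113.98),
                          sd = c(ASD = 16.90, TD = 16.69)),
    iq_nonverbal = list(mean = c(ASD = 119.75, TD = 117.03),
                        sd = c(ASD = 23.44, TD = 17.37)),
    p_female = c(ASD = 18 / 28, TD = 26 / 60)) {
  list(age = age, iq_crystalline = iq_crystalline,
       iq_nonverbal = iq_nonverbal, p_female = p_female)
}

#' Draw cohort covariates for a roster
#'
#' @param roster a `dyad_roster`.
#' @param config see [cohort_covariate_config()].
#' @param seed integer seed.
#' @return the roster with `sex`, `age`, `iq_crystalline`, `iq_nonverbal`
#'   filled for every participant.
#' @export
generate_cohort_covariates <- function(roster,
                                       config = cohort_covariate_config(),
                                       seed) {
  withr::with_seed(seed, {
    g <- roster$diagnosis
    draw <- function(par) stats::rnorm(nrow(roster), par$mean[g], par$sd[g])
    roster$age <- pmax(18, draw(config$age))
    roster$iq_crystalline <- draw(config$iq_crystalline)
    roster$iq_nonverbal <- draw(config$iq_nonverbal)
    roster$sex <- ifelse(stats::runif(nrow(roster)) < config$p_female[g],
                         "female", "male")
  })
  roster
}

#' Cohort group-comparison table
#'
#' Compares the ASD and TD diagnosis groups of a finalized roster: Wilcoxon
#' rank-sum tests for age and the two IQ measures with Benjamini-Hochberg
#' adjustment across the three tests, and a Yates-corrected chi-square test
#' of independence for sex x group. A Welch t-test variant is available for
#' the continuous covariates.
#'
#' @param roster a finalized `dyad_roster` with covariates.
#' @param continuous_test `"wilcoxon"` (default) or `"welch"`.
#' @return a list with `covariates` (data frame: covariate, statistic, p,
#'   p_adjusted) and `sex` (list: statistic, df, p, table).
#' @export
cohort_stats <- function(roster, continuous_test = c("wilcoxon", "welch")) {
  continuous_test <- match.arg(continuous_test)
  act <- active_roster(roster)
  if (!all(c("ASD", "TD") %in% act$diagnosis) ||
      any(table(act$diagnosis) == 0))
    stop_arg("cohort_stats needs both diagnosis groups non-empty")
  grp <- factor(act$diagnosis, levels = c("ASD", "TD"))
  covs <- c("age", "iq_crystalline", "iq_nonverbal")
  tests <- lapply(covs, function(v) {
    x <- act[[v]][grp == "ASD"]; y <- act[[v]][grp == "TD"]
    if (continuous_test == "wilcoxon")
      stats::wilcox.test(x, y, exact = FALSE)
    else
      stats::t.test(x, y, var.equal = FALSE)
  })
  p <- vapply(tests, function(t) t$p.value, numeric(1))
  covariates <- data.frame(
    covariate = covs,
    statistic = vapply(tests, function(t) unname(t$statistic), numeric(1)),
    p = p,
    p_adjusted = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
  tab <- table(sex = factor(act$sex, levels = c("female", "male")), group = grp)
  ch <- stats::chisq.test(tab, correct = TRUE)
  list(covariates = covariates,
       sex = list(statistic = unname(ch$statistic), df = unname(ch$parameter),
                  p = ch$p.value, table = tab))
}
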