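#' Dyad-grouped stratified nested cross-validation scheme
#'
#' Assigns dyads (never individuals) to folds so that both interactants
#' always share a fold, with class-stratified fold filling: per fold the
#' dyad count of each class is within one dyad of exact proportionality.
#' The outer level (CV2) has `outer_folds` folds repeated over
#' `outer_permutations` reshuffles; the inner level (CV1), used for
#' hyperparameter tuning only, is drawn inside each outer training set at
#' run time with the same assignment rule.
#'
#' @param labels a `label_vector` from [dyad_labels()] (labels must be
#'   constant within dyads).
#' @param outer_folds,outer_permutations CV2 geometry (defaults 11 and 10).
#' @param inner_folds,inner_permutations CV1 geometry (defaults 10 and 1).
#' @param seed integer seed.
#' @return an object of class `cv_scheme`: list with `dyads`, `dyad_label`,
#'   `participant_ids`, `group`, `outer_assignment` (dyads x permutations
#'   matrix of fold ids), and the geometry parameters.
#' @export
build_cv_scheme <- function(labels, outer_folds = 11, outer_permutations = 10,
                            inner_folds = 10, inner_permutations = 1, seed) {
  outer_folds <- check_count(outer_folds, "outer_folds", min = 2L)
  outer_permutations <- check_count(outer_permutations, "outer_permutations",
                                    min = 1L)
  inner_folds <- check_count(inner_folds, "inner_folds", min = 2L)
  inner_permutations <- check_count(inner_permutations, "inner_permutations",
                                    min = 1L)
  group <- labels$group
  lab <- labels$labels
  dyads <- unique(unname(group))
  dyad_label <- vapply(dyads, function(d) {
    l <- unique(as.character(lab[names(group)[group == d]]))
    if (length(l) != 1L)
      stop_arg("labels differ within dyad %s; dyad-grouped CV needs one label per dyad", d)
    l
  }, character(1))
  names(dyad_label) <- dyads
  cls_counts <- table(dyad_label)
  if (any(cls_counts < outer_folds))
    stop_arg("outer_folds (%d) exceeds the dyad count of class '%s' (%d)",
             outer_folds, names(cls_counts)[which.min(cls_counts)],
             min(cls_counts))
  assignment <- withr::with_seed(seed, {
    vapply(seq_len(outer_permutations), function(p)
      assign_stratified_folds(dyad_label, outer_folds),
      integer(length(dyads)))
  })
  assignment <- matrix(assignment, nrow = length(dyads),
                       dimnames = list(dyads, NULL))
  structure(list(dyads = dyads, dyad_label = dyad_label,
                 participant_ids = names(group), group = group,
                 outer_assignment = assignment,
                 outer_folds = outer_folds,
                 outer_permutations = outer_permutations,
                 inner_folds = inner_folds,
                 inner_permutations = inner_permutations,
                 seed = seed),
            class = "cv_scheme")
}

# Stratified grouped fold assignment by largest-remainder allocation: each
# class distributes its dyads as evenly as possible, remainders go to the
# currently lightest folds, so per-fold totals stay balanced too. Uses the
# RNG of the calling context (wrap in with_seed for determinism).
assign_stratified_folds <- function(dyad_label, k) {
  folds <- integer(length(dyad_label))
  loads <- integer(k)
  classes <- names(sort(table(dyad_label), decreasing = TRUE))
  for (cl in classes) {
    idx <- which(dyad_label == cl)
    idx <- idx[sample.int(length(idx))]
    base <- length(idx) %/% k
    rem <- length(idx) %% k
    counts <- rep(base, k)
    if (rem > 0) {
      ord <- order(loads, stats::runif(k))  # lightest folds first, random ties
      counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
    }
    folds[idx] <- rep(seq_len(k), counts)
    loads <- loads + counts
  }
  folds
}

#' @export
print.cv_scheme <- function(x, ...) {
  cat(sprintf("<cv_scheme> %d dyads (%s), CV2: %d folds x %d permutations, CV1: %d folds x %d\n",
              length(x$dyads),
              paste(sprintf("%s=%d", names(table(x$dyad_label)),
                            table(x$dyad_label)), collapse = ", "),
              x$outer_folds, x$outer_permutations,
              x$inner_folds, x$inner_permutations))
  invisible(x)
}

# participant-level fold ids for one outer permutation
participant_folds <- function(scheme, perm) {
  df <- scheme$outer_assignment[, perm]
  unname(df[scheme$group])
}
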