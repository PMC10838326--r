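#' Dyad-paired permutation test of a classification pipeline
#'
#' Assesses whether a model's balanced accuracy beats chance by rerunning
#' the full nested cross-validation under label permutations that respect
#' the dyadic structure: dyad-type labels are shuffled across dyads, so
#' both interactants always move together and class sizes are preserved
#' exactly. The p-value uses the add-one estimator
#' `p = (1 + #\{null BAC >= observed\}) / (1 + n_perm)`, which can never
#' return 0.
#'
#' @param features a `feature_set` or matrix with participant row names.
#' @param labels a `label_vector` ([dyad_labels()]).
#' @param n_perm number of permutations (>= 1; 1000 mirrors a full run,
#'   fewer for desk-scale work).
#' @param alpha significance level recorded with the result (default 0.05;
#'   results are additionally annotated at the stricter 0.005).
#' @param seed integer seed.
#' @param observed optional precomputed `model_result` for the unpermuted
#'   labels (recomputed when omitted).
#' @param outer_folds,outer_permutations,inner_folds CV geometry of each
#'   rerun; reduced-cost defaults (one outer permutation per null rerun)
#'   keep desk-scale runs tractable — pass `outer_permutations = 10` to
#'   mirror a full analysis.
#' @param C_grid regularization grid for each rerun; a single-value grid
#'   skips inner tuning.
#' @param kernel passed to [nested_cv_run()].
#' @return an object of class `permutation_result`: `observed_bac`,
#'   `null_bacs`, `p_value`, `n_perm`, `alpha`, `significant`,
#'   `significant_strict`.
#' @export
permutation_test <- function(features, labels, n_perm = 1000, alpha = 0.05,
                             seed = 1, observed = NULL,
                             outer_folds = 11, outer_permutations = 1,
                             inner_folds = 10, C_grid = default_c_grid(),
                             kernel = "linear") {
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  run <- function(lv, run_seed) {
    scheme <- build_cv_scheme(lv, outer_folds = outer_folds,
                              outer_permutations = outer_permutations,
                              inner_folds = inner_folds, seed = run_seed)
    nested_cv_run(features, lv, scheme, C_grid = C_grid,
                  seed = run_seed + 1L, kernel = kernel)
  }
  if (is.null(observed)) observed <- run(labels, seed)
  observed_bac <- observed$metrics$bac

  null_bacs <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    plab <- permute_dyad_labels(labels, seed + 7919L * i)
    null_bacs[i] <- run(plab, seed + i)$metrics$bac
  }
  p <- (1 + sum(null_bacs >= observed_bac)) / (1 + n_perm)
  structure(list(observed_bac = observed_bac, null_bacs = null_bacs,
                 p_value = p, n_perm = n_perm, alpha = alpha,
                 significant = p <= alpha,
                 significant_strict = p <= 0.005),
            class = "permutation_result")
}

#' Permute dyad-type labels across dyads
#'
#' Shuffles the dyad-level labels over dyads; both members of each dyad
#' inherit the same permuted label, so no draw ever splits a dyad and class
#' sizes are exactly preserved.
#'
#' @param labels a `label_vector`.
#' @param seed integer seed.
#' @return a `label_vector` with permuted labels.
#' @export
permute_dyad_labels <- function(labels, seed) {
  group <- labels$group
  dyads <- unique(unname(group))
  dlab <- vapply(dyads, function(d)
    as.character(labels$labels[names(group)[group == d]][1]), character(1))
  withr::with_seed(seed, perm <- sample(dlab))
  newlab <- factor(perm[match(unname(group), dyads)],
                   levels = levels(labels$labels))
  names(newlab) <- names(group)
  out <- labels
  out$labels <- newlab
  out
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed BAC %.1f%%, p = %.4g (%d permutations)%s%s\n",
              100 * x$observed_bac, x$p_value, x$n_perm,
              if (x$significant) sprintf(" *significant at %.3g", x$alpha) else "",
              if (x$significant_strict) " (also at 0.005)" else ""))
  invisible(x)
}

#' Stack base-model decision scores with a Gaussian-kernel SVM
#'
#' Second-level classifier over the base models' aggregated out-of-fold
#' decision scores, wrapped in the identical dyad-grouped nested CV
#' framework. The radial kernel width grid defaults to the median heuristic
#' times \{0.25, 0.5, 1, 2, 4\}.
#'
#' @param score_matrix participants x base-models matrix of out-of-fold
#'   decision scores (never training-fold scores), with participant row
#'   names; build it with [stacking_input()].
#' @param labels a `label_vector`.
#' @param scheme a `cv_scheme` (the same geometry as the base models).
#' @param C_grid regularization grid.
#' @param gamma_grid kernel width grid (default median heuristic x
#'   multipliers).
#' @param seed integer seed.
#' @return a `model_result` for the stacker.
#' @export
stack_models <- function(score_matrix, labels, scheme,
                         C_grid = default_c_grid(), gamma_grid = NULL,
                         seed = 1) {
  if (anyNA(score_matrix))
    stop_arg("stacking input contains missing scores")
  nested_cv_run(score_matrix, labels, scheme, C_grid = C_grid, seed = seed,
                kernel = "radial", gamma_grid = gamma_grid)
}

#' Assemble stacking input from base-model results
#'
#' @param results named list of `model_result`s.
#' @return participants x models matrix of aggregated out-of-fold decision
#'   scores.
#' @export
stacking_input <- function(results) {
  if (is.null(names(results)) || any(names(results) == ""))
    stop_arg("`results` must be a named list of model_result objects")
  ids <- names(results[[1]]$score)
  cols <- lapply(results, function(r) {
    if (!setequal(names(r$score), ids))
      stop_arg("model results cover different participants")
    r$score[ids]
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(ids, names(results))
  m
}

#' Feature-importance map from per-fold weight vectors
#'
#' For every feature: the mean weight across all CV models, the
#' cross-validation ratio (mean divided by the standard error across CV
#' models; infinite where the SE is zero, surfaced not hidden), and the
#' sign-based consistency (largest fraction of CV models agreeing on the
#' weight's sign, with exact zeros counting toward either sign).
#'
#' @param fold_weights models x features matrix of linear weight vectors
#'   (e.g. `model_result$fold_weights`), >= 2 rows.
#' @return data frame: `feature`, `mean_weight`, `se`, `cv_ratio`,
#'   `sign_consistency`.
#' @export
importance_map <- function(fold_weights) {
  if (is.null(fold_weights) || nrow(fold_weights) < 2L)
    stop_arg("importance_map needs >= 2 CV weight vectors")
  m <- nrow(fold_weights)
  mw <- colMeans(fold_weights)
  se <- apply(fold_weights, 2L, stats::sd) / sqrt(m)
  cvr <- ifelse(se == 0, ifelse(mw == 0, 0, Inf * sign(mw)), mw / se)
  consist <- pmax(colMeans(fold_weights >= 0), colMeans(fold_weights <= 0))
  data.frame(feature = colnames(fold_weights),
             mean_weight = unname(mw), se = unname(se),
             cv_ratio = unname(cvr),
             sign_consistency = unname(consist),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Correlate decision scores with covariates
#'
#' Pearson (or Spearman) correlation of a model's decision scores with each
#' covariate, Benjamini-Hochberg adjusted across covariates. Constant
#' covariates yield `NA` with a note, never an error.
#'
#' @param scores named numeric vector of decision scores.
#' @param covariates data frame of numeric covariates, rows aligned with
#'   `scores` (matched by row names when present).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data frame: `covariate`, `r`, `p`, `p_adjusted`, `note`.
#' @export
correlate_scores_covariates <- function(scores, covariates,
                                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  has_rn <- .row_names_info(as.data.frame(covariates)) > 0  # explicit names only
  if (has_rn && !is.null(names(scores))) {
    if (!setequal(rownames(covariates), names(scores)))
      stop_arg("scores and covariates cover different participants")
    covariates <- covariates[names(scores), , drop = FALSE]
  } else if (nrow(covariates) != length(scores)) {
    stop_arg("covariates rows (%d) != scores length (%d)",
             nrow(covariates), length(scores))
  }
  rows <- lapply(names(covariates), function(v) {
    x <- covariates[[v]]
    if (stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x)))
      return(data.frame(covariate = v, r = NA_real_, p = NA_real_,
                        note = "constant covariate",
                        stringsAsFactors = FALSE))
    ct <- stats::cor.test(scores, x, method = method, exact = FALSE)
    data.frame(covariate = v, r = unname(ct$estimate), p = ct$p.value,
               note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out[, c("covariate", "r", "p", "p_adjusted", "note")]
}

#' Write a model result to a run directory
#'
#' Persists the artifacts the reporting step consumes: decision scores
#' (participant, permutation, score), the metric panel as JSON, and the
#' per-fold weight vectors when available.
#'
#' @param result a `model_result`.
#' @param run_dir directory (created if needed).
#' @param name model name used in file names.
#' @return invisibly, the paths written.
#' @export
write_model_result <- function(result, run_dir, name) {
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  scores_path <- file.path(run_dir, paste0(name, "_scores.csv"))
  long <- data.frame(
    participant = rep(rownames(result$scores), ncol(result$scores)),
    permutation = rep(seq_len(ncol(result$scores)),
                      each = nrow(result$scores)),
    score = as.vector(result$scores))
  utils::write.csv(long, scores_path, row.names = FALSE)
  metrics_path <- file.path(run_dir, paste0(name, "_metrics.json"))
  writeLines(metrics_json(name, result$metrics), metrics_path)
  paths <- c(scores_path, metrics_path)
  if (!is.null(result$fold_weights)) {
    wpath <- file.path(run_dir, paste0(name, "_weights.csv"))
    utils::write.csv(as.data.frame(result$fold_weights), wpath,
                     row.names = FALSE)
    paths <- c(paths, wpath)
  }
  invisible(paths)
}

metrics_json <- function(name, m) {
  num <- function(x) if (is.na(x)) "null" else format(x, digits = 15)
  sprintf(paste0('{"model": "%s", "sensitivity": %s, "specificity": %s, ',
                 '"bac": %s, "auc": %s, "ppv": %s, "npv": %s}'),
          name, num(m$sensitivity), num(m$specificity), num(m$bac),
          num(m$auc), num(m$ppv), num(m$npv))
}

#' Human-readable report over a run directory
#'
#' Collects every `<model>_metrics.json` in the directory into a metric
#' table (one row per base or stacking model), appends permutation p-values
#' when `<model>_permutation.json` files are present, and is deterministic
#' given the artifacts.
#'
#' @param run_dir directory previously populated by [write_model_result()].
#' @return character vector of report lines (also of class `dyad_report`);
#'   errors with the expected file listing when the directory has no
#'   artifacts.
#' @export
report <- function(run_dir) {
  files <- sort(list.files(run_dir, pattern = "_metrics\\.json$",
                           full.names = TRUE))
  if (length(files) == 0L)
    stop_arg(paste0("no run artifacts in '%s'; expected files like ",
                    "<model>_metrics.json, <model>_scores.csv ",
                    "(written by write_model_result)"), run_dir)
  parse_num <- function(txt, key) {
    m <- regmatches(txt, regexec(paste0('"', key, '": ([-0-9.e+]+|null)'),
                                 txt))[[1]][2]
    if (is.na(m) || m == "null") NA_real_ else as.numeric(m)
  }
  rows <- lapply(files, function(f) {
    txt <- paste(readLines(f, warn = FALSE), collapse = "")
    nm <- regmatches(txt, regexec('"model": "([^"]*)"', txt))[[1]][2]
    data.frame(model = nm,
               bac = parse_num(txt, "bac"), auc = parse_num(txt, "auc"),
               sensitivity = parse_num(txt, "sensitivity"),
               specificity = parse_num(txt, "specificity"),
               ppv = parse_num(txt, "ppv"), npv = parse_num(txt, "npv"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  fmt <- function(x, pct = TRUE)
    ifelse(is.na(x), "  NA", sprintf(if (pct) "%5.1f" else "%5.2f",
                                     if (pct) 100 * x else x))
  lines <- c(
    "Model performance (out-of-fold, aggregated over outer permutations)",
    sprintf("%-12s %6s %6s %6s %6s %6s %6s",
            "model", "BAC%", "AUC", "sens%", "spec%", "PPV%", "NPV%"),
    sprintf("%-12s %6s %6s %6s %6s %6s %6s",
            tab$model, fmt(tab$bac), fmt(tab$auc, FALSE),
            fmt(tab$sensitivity), fmt(tab$specificity),
            fmt(tab$ppv), fmt(tab$npv)))
  perm_files <- sort(list.files(run_dir, pattern = "_permutation\\.json$",
                                full.names = TRUE))
  if (length(perm_files)) {
    lines <- c(lines, "", "Permutation tests (dyad-paired)")
    for (f in perm_files) {
      txt <- paste(readLines(f, warn = FALSE), collapse = "")
      nm <- regmatches(txt, regexec('"model": "([^"]*)"', txt))[[1]][2]
      lines <- c(lines, sprintf("%-12s observed BAC %5.1f%%  p = %.4g",
                                nm, 100 * parse_num(txt, "observed_bac"),
                                parse_num(txt, "p_value")))
    }
  }
  structure(lines, class = c("dyad_report", "character"))
}

#' @export
print.dyad_report <- function(x, ...) {
  cat(paste(x, collapse = "\n"), "\n")
  invisible(x)
}

#' Persist a permutation result next to a model's artifacts
#'
#' @param perm a `permutation_result`.
#' @param run_dir run directory.
#' @param name model name.
#' @return invisibly, the path written.
#' @export
write_permutation_result <- function(perm, run_dir, name) {
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(run_dir, paste0(name, "_permutation.json"))
  writeLines(sprintf(
    '{"model": "%s", "observed_bac": %s, "p_value": %s, "n_perm": %d}',
    name, format(perm$observed_bac, digits = 15),
    format(perm$p_value, digits = 15), perm$n_perm), path)
  invisible(path)
}
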