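#' Inverse-frequency class weights, normalized to mean 1
#'
#' @param y factor of class labels.
#' @return named numeric vector of per-class weights.
#' @export
inverse_frequency_weights <- function(y) {
  tab <- table(y)
  if (any(tab == 0)) tab <- tab[tab > 0]
  w <- as.numeric(sum(tab)) / (length(tab) * as.numeric(tab))
  w <- w / mean(w)
  stats::setNames(w, names(tab))
}

# Fit a class-weighted C-SVC and return an oriented scorer: positive
# decision values always point at levels(y)[1] (the positive class).
fit_svm <- function(X, y, C, kernel = "linear", gamma = NULL,
                    class_weights = NULL) {
  y <- droplevels(y)
  if (nlevels(y) < 2L) stop_arg("training labels contain a single class")
  if (is.null(class_weights)) class_weights <- inverse_frequency_weights(y)
  args <- list(x = X, y = y, kernel = kernel, cost = C, scale = FALSE,
               class.weights = class_weights, tolerance = 1e-6)
  if (kernel == "radial") args$gamma <- gamma
  model <- do.call(e1071::svm, args)
  # libsvm orders classes by first occurrence; read the orientation off the
  # decision-value column name "lev1/lev2" (positive value -> lev1)
  dv <- attr(stats::predict(model, X[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  first <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
  orient <- if (identical(first, levels(y)[1])) 1 else -1
  list(model = model, orient = orient, levels = levels(y),
       C = C, gamma = gamma, class_weights = class_weights)
}

svm_scores <- function(fit, X) {
  dv <- attr(stats::predict(fit$model, X, decision.values = TRUE),
             "decision.values")
  fit$orient * as.numeric(dv)
}

svm_linear_weights <- function(fit) {
  w <- fit$orient * drop(crossprod(fit$model$coefs, fit$model$SV))
  b <- fit$orient * (-fit$model$rho)
  list(weights = w, bias = b)
}

#' Train a class-weighted linear SVM
#'
#' Fits a linear support-vector classifier with per-class misclassification
#' costs (hyperplane weighting) correcting class imbalance. Positive
#' decision values indicate the first factor level of `y`.
#'
#' @param X numeric matrix, no missing values.
#' @param y factor with two levels (first level = positive class).
#' @param C regularization constant (> 0).
#' @param class_weights named per-class weights; default inverse frequency
#'   normalized to mean 1.
#' @return an object of class `linear_model`: list with `weights`, `bias`,
#'   `C`, `class_weights`, and `decision_function(X)`.
#' @export
train_weighted_linear_svm <- function(X, y, C = 1, class_weights = NULL) {
  if (anyNA(X)) stop_arg("X contains missing values; impute before training")
  if (C <= 0) stop_arg("`C` must be > 0")
  fit <- fit_svm(X, y, C, kernel = "linear", class_weights = class_weights)
  wb <- svm_linear_weights(fit)
  structure(list(weights = wb$weights, bias = wb$bias, C = C,
                 class_weights = fit$class_weights,
                 decision_function = function(Xnew)
                   drop(Xnew %*% wb$weights) + wb$bias,
                 fit = fit),
            class = "linear_model")
}

#' Classification metrics from decision scores
#'
#' Confusion-based metrics at a score threshold plus a rank-based AUC
#' (Mann-Whitney with midrank ties). `BAC = (sensitivity + specificity)/2`
#' holds exactly.
#'
#' @param truth factor of true labels; its first level is the positive
#'   class.
#' @param scores numeric decision scores, positive pointing at the positive
#'   class.
#' @param threshold decision threshold on the scores (default 0).
#' @return an object of class `clf_metrics`: named list `sensitivity`,
#'   `specificity`, `bac`, `auc`, `ppv`, `npv` (fractions in \[0, 1\]).
#' @export
compute_metrics <- function(truth, scores, threshold = 0) {
  if (any(!is.finite(scores))) stop_arg("scores must be finite")
  truth <- as.factor(truth)
  pos <- truth == levels(truth)[1]
  pred_pos <- scores > threshold
  tp <- sum(pos & pred_pos); fn <- sum(pos & !pred_pos)
  tn <- sum(!pos & !pred_pos); fp <- sum(!pos & pred_pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  bac <- if (is.na(sens)) spec else if (is.na(spec)) sens
         else (sens + spec) / 2
  auc <- if (any(pos) && any(!pos)) {
    r <- rank(scores)  # midranks for ties
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  } else NA_real_
  structure(list(sensitivity = sens, specificity = spec, bac = bac,
                 auc = auc,
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_),
            class = "clf_metrics")
}

#' @export
print.clf_metrics <- function(x, ...) {
  cat(sprintf("BAC %.1f%% | AUC %s | sens %.1f%% spec %.1f%% | PPV %s NPV %s\n",
              100 * x$bac,
              ifelse(is.na(x$auc), "NA", sprintf("%.2f", x$auc)),
              100 * x$sensitivity, 100 * x$specificity,
              ifelse(is.na(x$ppv), "NA", sprintf("%.1f%%", 100 * x$ppv)),
              ifelse(is.na(x$npv), "NA", sprintf("%.1f%%", 100 * x$npv))))
  invisible(x)
}

# preprocessing fitted on training rows only: per-feature z-standardization
# (NA-aware) followed by median imputation of remaining missing cells
fit_preprocessor <- function(Xtrain) {
  mu <- colMeans(Xtrain, na.rm = TRUE)
  sdv <- apply(Xtrain, 2L, stats::sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  mu[!is.finite(mu)] <- 0
  Z <- sweep(sweep(Xtrain, 2L, mu), 2L, sdv, "/")
  med <- apply(Z, 2L, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  list(mu = mu, sd = sdv, median = med)
}

apply_preprocessor <- function(pp, X) {
  Z <- sweep(sweep(X, 2L, pp$mu), 2L, pp$sd, "/")
  for (j in seq_len(ncol(Z))) Z[is.na(Z[, j]), j] <- pp$median[j]
  Z
}

#' Default regularization grid
#'
#' Eleven C values log-spaced from 2^-6 to 2^4.
#' @return numeric vector.
#' @export
default_c_grid <- function() 2^seq(-6, 4, length.out = 11)

#' Repeated nested cross-validation of a class-weighted SVM
#'
#' The outer (CV2) loop measures generalization only; everything else —
#' feature standardization, median imputation and hyperparameter selection —
#' happens strictly inside the outer training set. Per outer fold:
#' preprocessing is fitted on the training rows, the C (and, for the radial
#' kernel, gamma) maximizing mean inner-CV balanced accuracy is selected,
#' the model is refitted on the full outer training set, and decision scores
#' are produced for the held-out participants. Scores are aggregated across
#' outer permutations by their mean; predictions threshold the aggregated
#' score at 0.
#'
#' @param features a `feature_set` or bare numeric matrix with participant
#'   row names.
#' @param labels a `label_vector` aligned with the feature rows.
#' @param scheme a `cv_scheme` built on the same labels.
#' @param C_grid candidate regularization constants; when the grid has a
#'   single C (and single gamma) the inner loop is skipped.
#' @param seed integer seed (inner fold draws).
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param gamma_grid candidate kernel widths (radial kernel only).
#' @return an object of class `model_result`: out-of-fold `scores`
#'   (participants x outer permutations), aggregated `score`, `predicted`,
#'   `truth`, `metrics`, per-fold `fold_weights` (linear kernel),
#'   `chosen` parameter table, `positive_class`, `feature_names`.
#' @export
nested_cv_run <- function(features, labels, scheme,
                          C_grid = default_c_grid(), seed = 1,
                          kernel = c("linear", "radial"),
                          gamma_grid = NULL) {
  kernel <- match.arg(kernel)
  X <- if (inherits(features, "feature_set")) features$matrix else features
  if (is.null(rownames(X))) stop_arg("feature matrix needs participant row names")
  ids <- scheme$participant_ids
  if (!setequal(rownames(X), ids))
    stop_arg("feature rows and CV scheme cover different participants")
  X <- X[ids, , drop = FALSE]
  y <- labels$labels[ids]
  if (kernel == "radial" && is.null(gamma_grid))
    gamma_grid <- median_heuristic_gamma(X) * c(0.25, 0.5, 1, 2, 4)
  if (kernel == "linear") gamma_grid <- NA_real_
  param_grid <- expand.grid(C = C_grid, gamma = gamma_grid,
                            KEEP.OUT.ATTRS = FALSE)

  n <- length(ids)
  scores <- matrix(NA_real_, n, scheme$outer_permutations,
                   dimnames = list(ids, NULL))
  fold_weights <- list()
  chosen <- list()

  withr::with_seed(seed, {
    for (perm in seq_len(scheme$outer_permutations)) {
      pf <- participant_folds(scheme, perm)
      for (fold in seq_len(scheme$outer_folds)) {
        test <- pf == fold
        train <- !test
        pp <- fit_preprocessor(X[train, , drop = FALSE])
        Ztr <- apply_preprocessor(pp, X[train, , drop = FALSE])
        ytr <- y[train]
        best <- if (nrow(param_grid) == 1L) param_grid[1L, ] else
          tune_inner(Ztr, ytr, scheme$group[ids][train], scheme, param_grid)
        fit <- fit_svm(Ztr, ytr, C = best$C, kernel = kernel,
                       gamma = if (kernel == "radial") best$gamma else NULL)
        Zte <- apply_preprocessor(pp, X[test, , drop = FALSE])
        scores[test, perm] <- svm_scores(fit, Zte)
        if (kernel == "linear")
          fold_weights[[length(fold_weights) + 1L]] <-
            svm_linear_weights(fit)$weights
        chosen[[length(chosen) + 1L]] <-
          data.frame(permutation = perm, fold = fold, C = best$C,
                     gamma = best$gamma)
      }
    }
  })
  agg <- rowMeans(scores)
  predicted <- factor(ifelse(agg > 0, levels(y)[1], levels(y)[2]),
                      levels = levels(y))
  names(predicted) <- ids
  W <- if (length(fold_weights)) do.call(rbind, fold_weights) else NULL
  if (!is.null(W)) colnames(W) <- colnames(X)
  structure(list(scores = scores, score = agg, predicted = predicted,
                 truth = y, metrics = compute_metrics(y, agg),
                 fold_weights = W, chosen = do.call(rbind, chosen),
                 positive_class = labels$positive_class,
                 feature_names = colnames(X), kernel = kernel),
            class = "model_result")
}

# inner (CV1) hyperparameter search: dyad-grouped stratified folds inside
# the outer training set; BAC of pooled inner out-of-fold predictions
tune_inner <- function(Z, y, group, scheme, param_grid) {
  dyads <- unique(unname(group))
  dlab <- vapply(dyads, function(d)
    as.character(y[group == d][1]), character(1))
  k <- min(scheme$inner_folds, min(table(dlab)))
  bac <- matrix(NA_real_, nrow(param_grid), scheme$inner_permutations)
  for (ip in seq_len(scheme$inner_permutations)) {
    df <- assign_stratified_folds(stats::setNames(dlab, dyads), k)
    pf <- df[match(unname(group), dyads)]
    sc <- matrix(NA_real_, length(y), nrow(param_grid))
    for (fold in seq_len(k)) {
      tr <- pf != fold
      if (nlevels(droplevels(y[tr])) < 2L) next
      for (g in seq_len(nrow(param_grid))) {
        fit <- fit_svm(Z[tr, , drop = FALSE], y[tr], C = param_grid$C[g],
                       kernel = if (is.na(param_grid$gamma[g])) "linear"
                                else "radial",
                       gamma = param_grid$gamma[g])
        sc[!tr, g] <- svm_scores(fit, Z[!tr, , drop = FALSE])
      }
    }
    for (g in seq_len(nrow(param_grid))) {
      ok <- !is.na(sc[, g])
      if (any(ok))
        bac[g, ip] <- compute_metrics(y[ok], sc[ok, g])$bac
    }
  }
  mbac <- rowMeans(bac, na.rm = TRUE)
  # ties resolved toward the smallest C (strongest regularization first)
  best <- which(mbac == max(mbac, na.rm = TRUE))
  best <- best[order(param_grid$C[best], param_grid$gamma[best])][1]
  param_grid[best, ]
}

#' Median-heuristic kernel width
#'
#' `gamma = 1 / median(squared pairwise Euclidean distance)` over the rows
#' of `X` (missing cells ignored pairwise).
#' @param X numeric matrix.
#' @return positive scalar.
#' @export
median_heuristic_gamma <- function(X) {
  d2 <- stats::dist(X)^2
  m <- stats::median(d2[d2 > 0], na.rm = TRUE)
  if (!is.finite(m) || m == 0) 1 else 1 / m
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %d participants, %d outer permutations (%s kernel)\n",
              length(x$score), ncol(x$scores), x$kernel))
  print(x$metrics)
  invisible(x)
}
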