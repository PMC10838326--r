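test_that("cross-validation folds group dyads and stratify classes", {
  lab <- default_labels()
  scheme <- build_cv_scheme(lab, seed = 1)
  for (perm in 1:10) {
    pf <- dyadsync:::participant_folds(scheme, perm)
    # 44 dyads over 11 folds: exactly 4 dyads = 8 participants per test fold
    expect_equal(as.integer(table(pf)), rep(8L, 11))
    # both members of every dyad share a fold
    split_count <- sum(vapply(unique(unname(lab$group)), function(d) {
      length(unique(pf[lab$group == d])) > 1
    }, logical(1)))
    expect_equal(split_count, 0L)
    # per-fold class counts within one dyad of proportionality
    dl <- scheme$dyad_label
    fold_of_dyad <- scheme$outer_assignment[, perm]
    for (cl in unique(dl)) {
      per_fold <- table(factor(fold_of_dyad[dl == cl], levels = 1:11))
      expect_lte(max(per_fold) - min(per_fold), 1)
    }
  }
  expect_error(build_cv_scheme(default_labels(5, 3), outer_folds = 11,
                               seed = 1),
               "exceeds the dyad count")
})

test_that("fold grouping and stratification hold across many seeds and rosters", {
  for (s in 1:20) {
    n_mixed <- sample(12:30, 1)
    n_ctrl <- sample(8:20, 1)
    lab <- default_labels(n_mixed, n_ctrl, seed = s)
    k <- min(7, n_mixed, n_ctrl)
    scheme <- build_cv_scheme(lab, outer_folds = k, outer_permutations = 2,
                              seed = s)
    for (perm in 1:2) {
      pf <- dyadsync:::participant_folds(scheme, perm)
      for (d in unique(unname(lab$group)))
        expect_length(unique(pf[lab$group == d]), 1L)
      dl <- scheme$dyad_label
      fa <- scheme$outer_assignment[, perm]
      global <- table(dl) / length(dl)
      for (fold in 1:k) {
        cnt <- table(factor(dl[fa == fold], levels = names(global)))
        expect_true(all(abs(cnt - sum(cnt) * global) <= 1 + 1e-9))
      }
    }
  }
})

test_that("weighted linear SVM separates, flips with labels, and matches kernlab", {
  withr::with_seed(10, {
    X <- matrix(rnorm(60 * 4), 60, 4,
                dimnames = list(sprintf("p%02d", 1:60), paste0("f", 1:4)))
    y <- factor(rep(c("mixed", "control"), each = 30),
                levels = c("mixed", "control"))
    X[y == "mixed", 1:2] <- X[y == "mixed", 1:2] + 3
  })
  m <- train_weighted_linear_svm(X, y, C = 1)
  sc <- m$decision_function(X)
  expect_equal(compute_metrics(y, sc)$bac, 1)
  expect_equal(length(m$weights), 4L)

  yf <- factor(ifelse(y == "mixed", "control", "mixed"),
               levels = c("mixed", "control"))
  mf <- train_weighted_linear_svm(X, yf, C = 1)
  expect_equal(mf$weights, -m$weights, tolerance = 1e-4)
  expect_equal(mf$bias, -m$bias, tolerance = 1e-4)

  skip_if_not_installed("kernlab")
  km <- kernlab::ksvm(X, y, type = "C-svc", kernel = "vanilladot",
                      C = 1, scaled = FALSE)
  w_ref <- drop(crossprod(kernlab::coef(km)[[1]],
                          X[kernlab::alphaindex(km)[[1]], ]))
  # kernlab's positive direction may be either class; compare up to sign
  s <- sign(sum(w_ref * m$weights))
  expect_equal(s * w_ref, m$weights, tolerance = 1e-3)

  expect_error(train_weighted_linear_svm(X, factor(rep("a", 60))), "class")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(train_weighted_linear_svm(Xna, y), "missing")
})

test_that("duplicating minority samples approximates inverse-frequency weighting", {
  withr::with_seed(12, {
    X <- matrix(rnorm(90 * 3), 90, 3)
    y <- factor(rep(c("mixed", "control"), c(30, 60)),
                levels = c("mixed", "control"))
    X[y == "mixed", 1] <- X[y == "mixed", 1] + 1.5
  })
  w <- inverse_frequency_weights(y)
  expect_equal(mean(w), 1)
  expect_gt(w[["mixed"]], w[["control"]])
  m_w <- train_weighted_linear_svm(X, y, C = 0.5)
  Xdup <- rbind(X, X[y == "mixed", ], X[y == "mixed", ])
  ydup <- factor(c(as.character(y), rep("mixed", 60)),
                 levels = c("mixed", "control"))
  m_dup <- train_weighted_linear_svm(Xdup, ydup, C = 0.5,
                                     class_weights = c(mixed = 1, control = 1))
  ang <- sum(m_w$weights * m_dup$weights) /
    sqrt(sum(m_w$weights^2) * sum(m_dup$weights^2))
  expect_gt(ang, 0.98)
})

test_that("metrics follow the confusion arithmetic and the BAC identity", {
  # TP=20 FN=8 TN=20 FP=12
  truth <- factor(rep(c("mixed", "control"), c(28, 32)),
                  levels = c("mixed", "control"))
  scores <- c(rep(1, 20), rep(-1, 8), rep(-1, 20), rep(1, 12))
  m <- compute_metrics(truth, scores)
  expect_equal(round(m$sensitivity, 3), 0.714)
  expect_equal(round(m$specificity, 3), 0.625)
  expect_equal(round(m$bac, 3), 0.670)
  expect_equal(round(m$ppv, 3), 0.625)
  expect_equal(round(m$npv, 3), 0.714)
  expect_equal(m$bac, (m$sensitivity + m$specificity) / 2)

  expect_equal(compute_metrics(truth, ifelse(truth == "mixed", 2, -3))$auc, 1)
  expect_equal(compute_metrics(truth, ifelse(truth == "mixed", 2, -3))$bac, 1)

  # AUC is invariant under strictly monotone score transforms, and matches pROC
  withr::with_seed(3, sc <- rnorm(60))
  a1 <- compute_metrics(truth, sc)$auc
  expect_equal(compute_metrics(truth, exp(sc) + 5)$auc, a1)
  skip_if_not_installed("pROC")
  expect_equal(a1, as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = sc, levels = c("control", "mixed"),
    direction = "<", quiet = TRUE))))
})

test_that("nested CV is deterministic and keeps preprocessing inside the training folds", {
  lab <- default_labels(8, 6, seed = 4)
  X <- make_shifted_features(lab, p = 5, shift = 2, seed = 5)
  scheme <- build_cv_scheme(lab, outer_folds = 4, outer_permutations = 1,
                            inner_folds = 3, seed = 6)
  r1 <- nested_cv_run(X, lab, scheme, C_grid = c(0.1, 1), seed = 7)
  r2 <- nested_cv_run(X, lab, scheme, C_grid = c(0.1, 1), seed = 7)
  expect_identical(r1, r2)
  expect_equal(nrow(r1$chosen), 4)
  expect_equal(dim(r1$scores), c(28L, 1L))
  expect_true(all(!is.na(r1$scores)))
  expect_equal(unname(sign(r1$score) == 1),
               unname(r1$predicted == "mixed"))

  # corrupting the held-out rows of one fold leaves that fold's fitted
  # weights and chosen C unchanged (no leakage into preprocessing/tuning)
  pf <- dyadsync:::participant_folds(scheme, 1)
  fold1 <- rownames(X)[pf == 1]
  Xc <- X
  Xc[fold1, ] <- 1e6
  r3 <- nested_cv_run(Xc, lab, scheme, C_grid = c(0.1, 1), seed = 7)
  expect_equal(r3$fold_weights[1, ], r1$fold_weights[1, ])
  expect_equal(r3$chosen$C[1], r1$chosen$C[1])
  # while folds that train on the corrupted rows do change
  expect_false(isTRUE(all.equal(r3$fold_weights[2, ], r1$fold_weights[2, ])))
})

test_that("nested CV recovers a strong synthetic class separation", {
  lab <- default_labels()
  X <- make_shifted_features(lab, p = 5, shift = 3, seed = 8)
  scheme <- build_cv_scheme(lab, outer_permutations = 2, seed = 9)
  res <- nested_cv_run(X, lab, scheme, C_grid = 2^c(-4, 0, 4), seed = 10)
  expect_gte(res$metrics$bac, 0.9)
  expect_equal(res$metrics$bac,
               (res$metrics$sensitivity + res$metrics$specificity) / 2)
})
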