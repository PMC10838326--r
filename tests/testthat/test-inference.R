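test_that("dyad-paired label permutation never splits a dyad and keeps class sizes", {
  lab <- default_labels()
  for (s in 1:25) {
    pl <- permute_dyad_labels(lab, seed = s)
    expect_equal(as.integer(table(pl$labels)), as.integer(table(lab$labels)))
    for (d in unique(unname(pl$group)))
      expect_length(unique(pl$labels[names(pl$group)[pl$group == d]]), 1L)
  }
  expect_identical(permute_dyad_labels(lab, seed = 3),
                   permute_dyad_labels(lab, seed = 3))
})

test_that("permutation p-values follow the add-one estimator and never reach 0", {
  lab <- default_labels(8, 6, seed = 1)
  X <- make_shifted_features(lab, p = 4, shift = 4, seed = 2)
  pt <- permutation_test(X, lab, n_perm = 20, seed = 3,
                         outer_folds = 4, inner_folds = 3, C_grid = 1)
  expect_gt(pt$p_value, 0)
  expect_equal(pt$p_value,
               (1 + sum(pt$null_bacs >= pt$observed_bac)) / (1 + 20))
  expect_length(pt$null_bacs, 20)
  # a strongly separable problem beats every null draw
  expect_equal(pt$p_value, 1 / 21)
  expect_true(pt$significant)
  expect_error(permutation_test(X, lab, n_perm = 0, seed = 1), "n_perm")
})

test_that("p is non-increasing in the observed BAC for a fixed null sample", {
  null_bacs <- c(0.42, 0.5, 0.5, 0.55, 0.61)
  p_at <- function(obs) (1 + sum(null_bacs >= obs)) / (1 + length(null_bacs))
  obs_grid <- seq(0.3, 0.9, by = 0.05)
  ps <- vapply(obs_grid, p_at, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps > 0))
})

test_that("importance maps expose stability and sign consistency", {
  W <- rbind(c(1, 1, 0.5), c(1, -1, 0.5), c(1, 1, 0.5), c(1, -1, 0.5))
  colnames(W) <- c("a", "b", "c")
  im <- importance_map(W)
  expect_equal(im$sign_consistency, c(1, 0.5, 1))
  expect_true(is.infinite(im$cv_ratio[1]))
  expect_equal(im$mean_weight, c(1, 0, 0.5))

  withr::with_seed(4, Wr <- matrix(rnorm(20 * 6), 20, 6,
                                   dimnames = list(NULL, paste0("f", 1:6))))
  imr <- importance_map(Wr)
  expect_equal(imr$cv_ratio,
               unname(colMeans(Wr) / (apply(Wr, 2, sd) / sqrt(20))))
  expect_true(all(imr$sign_consistency >= 0.5 & imr$sign_consistency <= 1))
  expect_error(importance_map(Wr[1, , drop = FALSE]), ">= 2")
})

test_that("score-covariate correlations apply BH across covariates", {
  withr::with_seed(6, sc <- rnorm(40))
  names(sc) <- sprintf("P%02d", 1:40)
  cov <- data.frame(same = sc, negated = -sc, row.names = names(sc))
  out <- correlate_scores_covariates(sc, cov)
  expect_equal(out$r[out$covariate == "same"], 1)
  expect_equal(out$r[out$covariate == "negated"], -1)

  # BH on two raw p-values: both adjusted to the larger one when ordered
  withr::with_seed(7, cov2 <- data.frame(u = rnorm(40), v = rnorm(40)))
  out2 <- correlate_scores_covariates(sc, cov2)
  expect_equal(out2$p_adjusted, p.adjust(out2$p, "BH"))
  expect_equal(p.adjust(c(0.20, 0.23), "BH"), c(0.23, 0.23))

  cov3 <- data.frame(flat = rep(1, 40))
  out3 <- correlate_scores_covariates(sc, cov3)
  expect_true(is.na(out3$r))
  expect_match(out3$note, "constant")
})

test_that("stacking behaves sanely on degenerate and redundant inputs", {
  lab <- default_labels(10, 8, seed = 11)
  X <- make_shifted_features(lab, p = 4, shift = 3, seed = 12)
  scheme <- build_cv_scheme(lab, outer_folds = 5, outer_permutations = 2,
                            inner_folds = 3, seed = 13)
  base <- nested_cv_run(X, lab, scheme, C_grid = 2^c(-2, 0, 2), seed = 14)

  one <- stacking_input(list(base = base))
  stack1 <- stack_models(one, lab, scheme, C_grid = 2^c(-2, 0, 2), seed = 15)
  expect_lte(abs(stack1$metrics$bac - base$metrics$bac), 0.05)

  # a redundant duplicated column brings no gain over the single column
  two <- cbind(one, base = one[, 1])
  colnames(two) <- c("m1", "m2")
  stack2 <- stack_models(two, lab, scheme, C_grid = 2^c(-2, 0, 2), seed = 15)
  expect_lte(stack2$metrics$bac, stack1$metrics$bac + 0.05)

  # an informative column is never dragged to noise level by a noise column
  withr::with_seed(16, noise <- rnorm(nrow(one)))
  three <- cbind(one, noise = noise)
  colnames(three) <- c("m1", "noise")
  stack3 <- stack_models(three, lab, scheme, C_grid = 2^c(-2, 0, 2),
                         seed = 15)
  noise_only <- stack_models(matrix(noise, ncol = 1,
                                    dimnames = list(rownames(one), "noise")),
                             lab, scheme, C_grid = 2^c(-2, 0, 2), seed = 15)
  expect_gte(stack3$metrics$bac, noise_only$metrics$bac)

  bad <- one; bad[1] <- NA
  expect_error(stack_models(bad, lab, scheme), "missing")
})

test_that("report assembles a deterministic model table from artifacts", {
  lab <- default_labels(6, 5, seed = 21)
  X <- make_shifted_features(lab, p = 3, shift = 2.5, seed = 22)
  scheme <- build_cv_scheme(lab, outer_folds = 3, outer_permutations = 1,
                            inner_folds = 2, seed = 23)
  res <- nested_cv_run(X, lab, scheme, C_grid = 1, seed = 24)

  run_dir <- withr::local_tempdir()
  models <- c("FACEsync", "HEADsync", "BODYsync", "INTRAsync", "MovEx",
              "stack_head", "stack_all")
  for (m in models) write_model_result(res, run_dir, m)
  pt <- permutation_test(X, lab, n_perm = 5, seed = 25, observed = res,
                         outer_folds = 3, inner_folds = 2, C_grid = 1)
  write_permutation_result(pt, run_dir, "FACEsync")

  rep1 <- report(run_dir)
  expect_s3_class(rep1, "dyad_report")
  # 7 model rows after the two header lines
  expect_length(grep("^(FACEsync|HEADsync|BODYsync|INTRAsync|MovEx|stack_)",
                     rep1), 8)  # 7 metric rows + 1 permutation row
  expect_identical(report(run_dir), rep1)
  expect_error(report(withr::local_tempdir()), "expected files")
})
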