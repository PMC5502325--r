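test_that("cv plan partitions subjects with balanced folds and strata", {
  y <- toy_labels(163, 11, seed = 2)
  plan <- make_cv_plan(y, n_folds = 5, n_repeats = 10, seed = 3)
  for (r in 1:10) {
    fold <- plan$assignments[, r]
    expect_setequal(unique(fold), 1:5)
    expect_setequal(sort(table(fold)), c(32, 32, 33, 33, 33))
    pos_per_fold <- table(factor(fold[y == 1], levels = 1:5))
    expect_true(all(pos_per_fold %in% 2:3))   # 11 positives over 5 folds
  }
  # reproducibility and distinctness across repeats
  plan2 <- make_cv_plan(y, n_folds = 5, n_repeats = 10, seed = 3)
  expect_identical(plan$assignments, plan2$assignments)
  expect_false(identical(plan$assignments[, 1], plan$assignments[, 2]))

  expect_error(make_cv_plan(toy_labels(4, 2), n_folds = 5), "folds")
  expect_warning(make_cv_plan(toy_labels(30, 2), n_folds = 5), "positives")
})

test_that("inner selection returns the degenerate and the best grid point", {
  X <- toy_cohort(60, 4, seed = 6)
  y <- toy_labels(60, 20, seed = 6)
  one <- default_family_grids("logistic")$logistic
  expect_identical(inner_select(X, y, one)$spec$family, "logistic")

  # a linear signal: the linear kernel should beat a polynomial kernel
  # more often than not across simulated cohorts
  set.seed(44)
  wins <- replicate(8, {
    n <- 150
    Xs <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
    ys <- rbinom(n, 1, plogis(1.5 * Xs[, 1] - 1.2 * Xs[, 2]))
    grid <- list(model_spec("svm_linear", cost = 1, class_weight = TRUE),
                 model_spec("svm_poly", cost = 1, degree = 3,
                            class_weight = TRUE))
    inner_select(Xs, ys, grid, seed = sample.int(1e6, 1))$spec$family
  })
  expect_gt(mean(wins == "svm_linear"), 0.5)
})

test_that("rnncv is deterministic and reports coherent summaries", {
  sp <- synthetic_spec(n_subjects = 80, n_variables = 12, n_parents = 2,
                       parent_effects = c(2, 2), target_prevalence = 0.2,
                       n_correlated_distractors = 2, missing_rate = 0,
                       high_missing_columns = 0, seed = 19)
  g <- generate_cohort(sp)
  fams <- default_family_grids(c("lasso", "logistic"), reduced = TRUE)
  r1 <- suppressWarnings(run_rnncv(g$table, g$target, families = fams,
                                   n_repeats = 3, seed = 5,
                                   preprocess = FALSE))
  r2 <- suppressWarnings(run_rnncv(g$table, g$target, families = fams,
                                   n_repeats = 3, seed = 5,
                                   preprocess = FALSE))
  expect_identical(r1$estimates$lasso$per_repeat_auc,
                   r2$estimates$lasso$per_repeat_auc)
  est <- r1$estimates$lasso
  expect_equal(est$mean_auc, mean(est$per_repeat_auc))
  expect_equal(est$sd_auc, sd(est$per_repeat_auc))
  expect_length(est$per_repeat_auc, 3)
  # planted signal at 20% prevalence should be learnable
  expect_gt(est$mean_auc, 0.6)
})

test_that("rnncv handles missing data through fold-wise preprocessing", {
  sp <- synthetic_spec(n_subjects = 70, n_variables = 10, n_parents = 2,
                       parent_effects = c(1.5, 1.5), target_prevalence = 0.25,
                       n_correlated_distractors = 0, missing_rate = 0.08,
                       high_missing_columns = 1, seed = 77)
  g <- generate_cohort(sp)
  res <- suppressWarnings(
    run_rnncv(g$table, g$target,
              families = default_family_grids("logistic"),
              n_repeats = 2, seed = 9, impute_k = 5))
  expect_true(is.finite(res$estimates$logistic$mean_auc))
  expect_error(run_rnncv(g$table, g$target, preprocess = FALSE),
               "missing")
})

test_that("fold-internal feature selection records per-fold PC sets", {
  sp <- synthetic_spec(n_subjects = 120, n_variables = 15, n_parents = 2,
                       parent_effects = c(2, 2), target_prevalence = 0.25,
                       n_correlated_distractors = 2, missing_rate = 0,
                       high_missing_columns = 0, seed = 31)
  g <- generate_cohort(sp)
  res <- suppressWarnings(
    run_rnncv(g$table, g$target,
              families = default_family_grids("logistic"),
              feature_selection = "hiton",
              n_repeats = 1, seed = 2, preprocess = FALSE))
  expect_length(res$selected_features, 5)   # one PC set per outer fold
  sel <- unlist(res$selected_features)
  # strong planted parents dominate fold-wise selections
  expect_gt(mean(sel %in% g$truth$parents), 0.5)
})
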