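test_that("generation is deterministic in the seed", {
  sp <- synthetic_spec(seed = 5)
  g1 <- generate_cohort(sp)
  g2 <- generate_cohort(sp)
  expect_identical(g1$table$values, g2$table$values)
  expect_identical(g1$target$labels, g2$target$labels)
  g3 <- generate_cohort(synthetic_spec(seed = 6))
  expect_false(identical(g1$target$labels, g3$target$labels))
})

test_that("marginal prevalence is calibrated to the spec", {
  pos <- vapply(1:60, function(i) {
    g <- generate_cohort(synthetic_spec(n_subjects = 163, n_variables = 20,
                                        seed = 1000 + i))
    sum(g$target$labels)
  }, numeric(1))
  prev <- sum(pos) / (60 * 163)
  se <- sqrt(0.07 * 0.93 / (60 * 163))
  # 3 binomial SEs plus the 0.002 intercept-solver tolerance
  expect_lt(abs(prev - 0.07), 3 * se + 0.002)
})

test_that("cohort structure matches its ground truth", {
  sp <- synthetic_spec(seed = 9)
  g <- generate_cohort(sp)
  tr <- g$truth
  expect_length(tr$parents, 5)
  expect_length(tr$distractor_map, 10)
  expect_length(intersect(tr$parents, tr$noise_variables), 0)
  expect_true(all(tr$distractor_map %in% tr$parents))
  expect_equal(ncol(g$table$values), 105)
  expect_equal(nrow(g$table$values), 163)
  # forced high-missingness columns exceed the 50% filter threshold
  frac <- colMeans(g$table$missing)
  expect_equal(sum(frac > 0.5), 3)
  # distractors correlate with their parents
  for (d in names(tr$distractor_map)) {
    keep <- !g$table$missing[, d] & !g$table$missing[, tr$distractor_map[d]]
    expect_gt(abs(cor(g$table$values[keep, d],
                      g$table$values[keep, tr$distractor_map[d]])), 0.3)
  }
})

test_that("missingness is label-independent (MCAR)", {
  rates <- t(vapply(1:20, function(i) {
    g <- generate_cohort(synthetic_spec(n_subjects = 200, n_variables = 30,
                                        target_prevalence = 0.3,
                                        high_missing_columns = 0,
                                        seed = 400 + i))
    y <- g$target$labels
    c(case = mean(g$table$missing[y == 1, ]),
      control = mean(g$table$missing[y == 0, ]))
  }, numeric(2)))
  expect_lt(abs(mean(rates[, "case"]) - mean(rates[, "control"])), 0.01)
})

test_that("bayes AUC behaves at the limits and tracks effect size", {
  null_truth <- generate_cohort(
    synthetic_spec(parent_effects = rep(0, 5), seed = 3))$truth
  expect_equal(null_truth$bayes_auc, 0.5)
  expect_equal(bayes_auc_oracle(null_truth)$auc, 0.5)

  huge <- generate_cohort(
    synthetic_spec(n_parents = 1, parent_effects = 20,
                   kind_mix = c(binary = 0, categorical = 0, continuous = 1),
                   n_correlated_distractors = 0, seed = 3))$truth
  expect_gt(huge$bayes_auc, 0.95)

  # monotone: larger effects never lower the optimum
  aucs <- vapply(c(0.2, 0.6, 1.2), function(b) {
    generate_cohort(synthetic_spec(n_variables = 10, n_parents = 2,
                                   parent_effects = rep(b, 2),
                                   n_correlated_distractors = 0,
                                   seed = 3))$truth$bayes_auc
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("bayes AUC matches a numeric-integration oracle", {
  # single standard-normal parent with effect b: the case/control score
  # densities are f1(s) ~ plogis(b0+s) phi(s/b)/b and f0 its complement;
  # integrate P(S1 > S0) on a grid
  b <- 0.9
  tr <- generate_cohort(
    synthetic_spec(n_parents = 1, parent_effects = b,
                   kind_mix = c(binary = 0, categorical = 0, continuous = 1),
                   n_correlated_distractors = 0, seed = 21))$truth
  b0 <- tr$intercept
  s <- seq(-8 * b, 8 * b, length.out = 4001)
  w <- dnorm(s, 0, b); w <- w / sum(w)
  p1 <- plogis(b0 + s)
  prev <- sum(w * p1)
  f1 <- w * p1 / prev
  f0 <- w * (1 - p1) / (1 - prev)
  F0 <- cumsum(f0)
  auc_int <- sum(f1 * (F0 - 0.5 * f0))
  orc <- bayes_auc_oracle(tr, n_mc = 8e4, seed = 5)
  expect_lt(abs(orc$auc - auc_int), 2 * orc$se + 0.002)
  expect_lt(abs(tr$bayes_auc - auc_int), 0.02)
})

test_that("the default spec sits in the intended signal regime", {
  g <- generate_cohort(synthetic_spec(seed = 17))
  expect_gt(g$truth$bayes_auc, 0.75)
  expect_lt(g$truth$bayes_auc, 0.85)
})

test_that("large-sample logistic fit recovers effect signs and ranks", {
  sp <- synthetic_spec(n_subjects = 20000, n_variables = 12, n_parents = 4,
                       parent_effects = c(0.9, 0.6, 0.4, 0.2),
                       n_correlated_distractors = 0,
                       kind_mix = c(binary = 0, categorical = 0,
                                    continuous = 1),
                       missing_rate = 0, high_missing_columns = 0,
                       seed = 71)
  g <- generate_cohort(sp)
  X <- g$table$values[, g$truth$parents]
  fit <- glm(g$target$labels ~ X, family = binomial)
  beta_hat <- coef(fit)[-1]
  names(beta_hat) <- colnames(X)
  expect_true(all(beta_hat > 0))
  expect_equal(order(-beta_hat), order(-g$truth$effects))
})

test_that("zero-effect cohorts drive HITON-PC to empty selections usually", {
  hits <- vapply(1:8, function(i) {
    g <- generate_cohort(synthetic_spec(n_variables = 20,
                                        parent_effects = rep(0, 5),
                                        missing_rate = 0,
                                        high_missing_columns = 0,
                                        seed = 600 + i))
    length(run_hiton_pc(g$table, g$target)$selected)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.5)
})

test_that("synthetic cohorts round-trip through the cohort file format", {
  g <- generate_cohort(synthetic_spec(n_subjects = 30, n_variables = 8,
                                      n_parents = 2,
                                      n_correlated_distractors = 2,
                                      high_missing_columns = 1, seed = 2))
  path <- tempfile(fileext = ".tsv")
  truth_path <- tempfile(fileext = ".json")
  write_synthetic(g, path, truth_path)
  back <- read_cohort(path, quiet = TRUE)$table
  expect_equal(back$values, g$table$values, ignore_attr = TRUE)
  tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  expect_equal(tr$parents, g$truth$parents)
})
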