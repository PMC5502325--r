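test_that("the add-one permutation p matches hand counting", {
  expect_equal(permutation_p(0.55, c(0.4, 0.5, 0.6)), (1 + 1) / (1 + 3))
  expect_equal(permutation_p(0.39, c(0.4, 0.5, 0.6)), 1)
  expect_equal(permutation_p(0.7, c(0.4, 0.5, 0.6)), 0.25)
  # observed below the null median -> p > 0.5
  expect_gt(permutation_p(0.45, c(0.4, 0.5, 0.6)), 0.5)
  # ties count as "equal or higher"
  expect_equal(permutation_p(0.5, c(0.4, 0.5, 0.6)), 0.75)
})

test_that("label shuffling keeps the protocol honest on noise", {
  sp <- synthetic_spec(n_subjects = 80, n_variables = 10,
                       parent_effects = rep(0, 5),
                       n_correlated_distractors = 0,
                       target_prevalence = 0.15,
                       missing_rate = 0, high_missing_columns = 0,
                       seed = 61)
  g <- generate_cohort(sp)
  expect_warning(
    perm <- label_shuffle_test(g$table, g$target, observed_auc = 0.55,
                               families = default_family_grids("lasso",
                                                               reduced = TRUE),
                               n_permutations = 12, null_repeats = 1,
                               seed = 4, preprocess = FALSE),
    "resolution")
  expect_length(perm$null_aucs, 12)
  expect_equal(perm$p_one_sided,
               permutation_p(0.55, perm$null_aucs))
  expect_equal(perm$null_ci95,
               unname(quantile(perm$null_aucs, c(0.025, 0.975))))
  # unbiased protocol: null mean near one half
  expect_lt(abs(perm$null_mean - 0.5), 0.08)
})

test_that("bootstrap stability counts, thresholds and ranks correctly", {
  sp <- synthetic_spec(n_subjects = 150, n_variables = 12, n_parents = 2,
                       parent_effects = c(2.5, 2.5), target_prevalence = 0.3,
                       n_correlated_distractors = 0, missing_rate = 0,
                       high_missing_columns = 0, seed = 83)
  g <- generate_cohort(sp)
  prof <- bootstrap_stability(g$table, g$target, B = 20,
                              threshold_count = 5, seed = 11,
                              preprocess = FALSE)
  expect_true(all(prof$frequencies >= 0 & prof$frequencies <= 20))
  expect_setequal(prof$stable_set,
                  names(prof$frequencies)[prof$frequencies > 5])
  # strong parents should be the most stable variables
  rk <- rank_stable(prof)
  expect_true(all(g$truth$parents %in% rk$variable[1:3]))
  expect_true(all(diff(rk$frequency) <= 0))

  # B = 1 degenerates to indicator frequencies
  prof1 <- bootstrap_stability(g$table, g$target, B = 1, seed = 2,
                               preprocess = FALSE)
  expect_true(all(prof1$frequencies %in% c(0L, 1L)))
})

test_that("rank_stable breaks frequency ties lexicographically", {
  prof <- structure(list(frequencies = c(beta = 30L, alpha = 30L, z = 5L),
                         B = 100L, threshold_count = 20L,
                         stable_set = c("beta", "alpha")),
                    class = "stability_profile")
  rk <- rank_stable(prof)
  expect_equal(rk$variable, c("alpha", "beta", "z"))
  expect_equal(rk$stable, c(TRUE, TRUE, FALSE))
})

test_that("information overlap splits bootstrap frequency between copies", {
  # one lone parent and one parent shadowed by a near-duplicate: the lone
  # parent should be selected at least as often as either member of the
  # overlapping pair
  sp <- synthetic_spec(n_subjects = 500, n_variables = 10, n_parents = 2,
                       parent_effects = c(1.5, 1.5), target_prevalence = 0.2,
                       n_correlated_distractors = 1,
                       distractor_correlation = 0.95,
                       kind_mix = c(binary = 0, categorical = 0,
                                    continuous = 1),
                       missing_rate = 0, high_missing_columns = 0,
                       seed = 29)
  g <- generate_cohort(sp)
  shadowed <- unname(g$truth$distractor_map)       # parent with a copy
  lone <- setdiff(g$truth$parents, shadowed)
  dup <- names(g$truth$distractor_map)
  prof <- bootstrap_stability(g$table, g$target, B = 25, seed = 3,
                              preprocess = FALSE)
  f <- prof$frequencies
  expect_gte(f[lone], max(f[shadowed], f[dup]))
})

test_that("pure-noise data yields uniformly low stability", {
  sp <- synthetic_spec(n_subjects = 120, n_variables = 15,
                       parent_effects = rep(0, 5), target_prevalence = 0.15,
                       missing_rate = 0, high_missing_columns = 0,
                       seed = 47)
  g <- generate_cohort(sp)
  prof <- bootstrap_stability(g$table, g$target, B = 20, seed = 13,
                              preprocess = FALSE)
  expect_lt(max(prof$frequencies) / prof$B, 0.6)
})
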