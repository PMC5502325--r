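test_that("AUC matches brute-force pair counting and the worked example", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # tie counted one half: (1 + 1 + 0.5 + 1) / 4
  expect_equal(compute_auc(c(0.7, 0.5, 0.5, 0.3), c(1, 1, 0, 0)), 0.875)
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)   # force some ties
    y <- toy_labels(n, sample(seq_len(n - 1), 1), seed = rep)
    expect_equal(compute_auc(s, y), pair_auc(s, y))
  }
  expect_error(compute_auc(1:4, c(1, 1, 1, 1)), "single class")
})

test_that("AUC is invariant to monotone transforms and flips with labels", {
  set.seed(8)
  s <- rnorm(40); y <- toy_labels(40, 10)
  a <- compute_auc(s, y)
  expect_equal(compute_auc(exp(s), y), a)
  expect_equal(compute_auc(qlogis(plogis(s)), y), a)
  expect_equal(compute_auc(s, 1 - y), 1 - a)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  s <- rnorm(60); y <- toy_labels(60, 15)
  expect_equal(compute_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("every family separates a linearly separable toy", {
  set.seed(2)
  X <- rbind(matrix(rnorm(60, -2, 0.5), 30, 2),
             matrix(rnorm(60, 2, 0.5), 30, 2))
  colnames(X) <- c("a", "b")
  y <- rep(c(0L, 1L), each = 30)
  Xt <- rbind(c(-2.5, -2.5), c(-1.5, -2), c(2, 1.5), c(2.5, 2.5))
  colnames(Xt) <- c("a", "b")
  for (fam in c("svm_linear", "svm_poly", "svm_rbf", "random_forest",
                "lasso", "logistic", "stepwise_logistic")) {
    s <- fit_score(model_spec(fam, cost = 1, lambda = 0.01,
                              class_weight = TRUE), X, y, Xt)
    expect_gt(min(s[3:4]), max(s[1:2]), label = fam)
  }
})

test_that("infinite lasso penalty zeroes all weights", {
  set.seed(3)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- rbinom(50, 1, plogis(X[, 1]))
  s <- fit_score(model_spec("lasso", lambda = 1e6), X, y, X)
  expect_equal(length(unique(round(s, 10))), 1)
})

test_that("logistic scores are monotone in a single feature", {
  set.seed(4)
  x <- matrix(sort(rnorm(80)), dimnames = list(NULL, "x"))
  y <- rbinom(80, 1, plogis(2 * x))
  s <- fit_score(model_spec("logistic"), x, y, x)
  expect_true(all(diff(s) >= 0))
})

test_that("single-class training data is a hard error", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_score(model_spec("logistic"), X, rep(1L, 10), X),
               "single-class")
})

test_that("stepwise selection finds planted signal and rejects pure noise", {
  set.seed(17)
  n <- 500
  X <- matrix(rnorm(n * 11), n, 11,
              dimnames = list(NULL, sprintf("v%02d", 1:11)))
  y <- rbinom(n, 1, plogis(-1 + 1.5 * X[, 6]))
  expect_true("v06" %in% stepwise_select(X, y))

  Xn <- matrix(rnorm(200 * 8), 200, 8,
               dimnames = list(NULL, sprintf("n%d", 1:8)))
  # with 8 noise candidates the expected number of spurious AIC-improving
  # additions is about 8 * P(chisq_1 > 2) ~ 1.3; a large subset would
  # indicate a broken criterion
  yn <- toy_labels(200, 40, seed = 90)
  expect_lte(length(stepwise_select(Xn, yn)), 3)
})

test_that("stepwise result is locally optimal and matches exhaustive search", {
  # independent AIC via stats::glm on every candidate subset
  glm_aic <- function(X, y, sel) {
    df <- data.frame(y = y, X[, sel, drop = FALSE])
    fml <- if (length(sel)) stats::as.formula(paste("y ~", paste(sel, collapse = "+")))
           else y ~ 1
    stats::AIC(suppressWarnings(stats::glm(fml, binomial, df)))
  }
  set.seed(23)
  for (rep in 1:5) {
    n <- 150
    X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- rbinom(n, 1, plogis(-0.5 + 1.2 * X[, 1] + 0.8 * X[, 3]))
    sel <- stepwise_select(X, y)
    aic_sel <- glm_aic(X, y, sel)
    # no single add or remove improves the criterion (hill-climb contract)
    for (v in setdiff(colnames(X), sel))
      expect_gte(glm_aic(X, y, c(sel, v)), aic_sel - 1e-6)
    for (v in sel)
      expect_gte(glm_aic(X, y, setdiff(sel, v)), aic_sel - 1e-6)
    # and here the hill-climb attains the global optimum over all 2^4 subsets
    subsets <- unlist(lapply(0:4, function(k)
      utils::combn(colnames(X), k, simplify = FALSE)), recursive = FALSE)
    best <- min(vapply(subsets, function(s) glm_aic(X, y, s), numeric(1)))
    expect_equal(aic_sel, best, tolerance = 1e-6)
  }
})

test_that("model specs survive a JSON round trip", {
  spec <- model_spec("svm_rbf", cost = 10, gamma = 0.1, class_weight = TRUE,
                     feature_subset = c("a", "b"))
  back <- spec_from_json(spec_to_json(spec))
  expect_equal(back$family, spec$family)
  expect_equal(back$hyper, spec$hyper)
  expect_equal(back$feature_subset, spec$feature_subset)
})
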