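#' Classifier model specification
#'
#' A lightweight description of one point in a family's hyperparameter
#' grid, the unit the inner model-selection loop searches over.
#'
#' @param family One of `"svm_linear"`, `"svm_poly"`, `"svm_rbf"`,
#'   `"random_forest"`, `"lasso"`, `"logistic"`, `"stepwise_logistic"`.
#' @param ... Named hyperparameters (e.g. `cost`, `gamma`, `degree`,
#'   `lambda`, `ntree`, `mtry`, `class_weight`).
#' @param feature_subset Optional character vector restricting the model to
#'   named variables.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family, ..., feature_subset = NULL) {
  family <- match.arg(family, c("svm_linear", "svm_poly", "svm_rbf",
                                "random_forest", "lasso", "logistic",
                                "stepwise_logistic"))
  structure(list(family = family, hyper = list(...),
                 feature_subset = feature_subset),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  h <- if (length(x$hyper))
    paste(names(x$hyper), unlist(x$hyper), sep = "=", collapse = ", ")
  else "defaults"
  cat(sprintf("model_spec: %s (%s)\n", x$family, h))
  invisible(x)
}

#' Serialize / restore a model spec as JSON
#' @param spec A `model_spec`.
#' @return JSON string.
#' @export
spec_to_json <- function(spec) {
  jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, null = "null")
}

#' @rdname spec_to_json
#' @param json JSON string from [spec_to_json()].
#' @export
spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  do.call(model_spec, c(list(family = x$family),
                        as.list(x$hyper),
                        list(feature_subset = x$feature_subset)))
}

#' Default hyperparameter grids per classifier family
#'
#' The grids searched by the inner model-selection loop. Margin and
#' likelihood classifiers (`svm_*`, `logistic`) use inverse-prevalence
#' class weighting by default, since at a 7% case rate unweighted margins
#' degenerate toward the majority class; the flag is carried in every spec
#' so the choice is logged.
#'
#' @param families Character vector of families to include (default all
#'   seven).
#' @param reduced Logical; `TRUE` gives a small screening grid (used for
#'   large simulation studies), `FALSE` the full default grid.
#' @return Named list mapping family to a list of [model_spec()]s.
#' @export
default_family_grids <- function(families = c("svm_linear", "svm_poly",
                                              "svm_rbf", "random_forest",
                                              "lasso", "logistic",
                                              "stepwise_logistic"),
                                 reduced = FALSE) {
  costs <- if (reduced) c(0.1, 1, 10) else c(0.01, 0.1, 1, 10, 100)
  gammas <- if (reduced) c(0.01, 0.1) else c(0.01, 0.1, 1, 10)
  degrees <- if (reduced) 2 else 2:3
  lambdas <- exp(seq(log(1e-4), log(10),
                     length.out = if (reduced) 8 else 20))
  grids <- list(
    svm_linear = lapply(costs, function(C)
      model_spec("svm_linear", cost = C, class_weight = TRUE)),
    svm_poly = do.call(c, lapply(degrees, function(d)
      lapply(costs, function(C)
        model_spec("svm_poly", cost = C, degree = d, class_weight = TRUE)))),
    svm_rbf = do.call(c, lapply(gammas, function(g)
      lapply(if (reduced) c(1, 10) else costs, function(C)
        model_spec("svm_rbf", cost = C, gamma = g, class_weight = TRUE)))),
    random_forest = if (reduced)
      list(model_spec("random_forest", ntree = 200, mtry_rule = "sqrt"))
    else lapply(c("sqrt", "third"), function(m)
      model_spec("random_forest", ntree = 500, mtry_rule = m)),
    lasso = lapply(lambdas, function(l) model_spec("lasso", lambda = l)),
    logistic = list(model_spec("logistic", class_weight = TRUE)),
    stepwise_logistic = list(model_spec("stepwise_logistic",
                                        class_weight = FALSE,
                                        max_steps = if (reduced) 6 else 20))
  )
  grids[families]
}

# inverse-prevalence observation weights (mean 1)
class_weights <- function(y) {
  w <- ifelse(y == 1, 1 / mean(y == 1), 1 / mean(y == 0)) / 2
  w / mean(w)
}

#' Fit one classifier and score held-out subjects
#'
#' Uniform adapter over the seven families: fits the spec on the training
#' data and returns a continuous decision score per test subject, oriented
#' so that higher means more case-like (SVM margin, random-forest vote
#' fraction, or linear predictor). Test labels are never consulted.
#'
#' @param spec A [model_spec()].
#' @param train_x Training [cohort_table()] or numeric matrix (complete,
#'   normalized).
#' @param train_y Training labels (`target_vector` or 0/1), both classes
#'   present.
#' @param test_x Held-out table/matrix with the same variables.
#' @return Numeric score vector aligned to the rows of `test_x`.
#' @export
fit_score <- function(spec, train_x, train_y, test_x) {
  X <- as_values(train_x); Xt <- as_values(test_x)
  y <- as_labels(train_y)
  if (length(unique(y)) < 2) stop("single-class training data")
  if (!is.null(spec$feature_subset)) {
    X <- X[, spec$feature_subset, drop = FALSE]
    Xt <- Xt[, spec$feature_subset, drop = FALSE]
  }
  h <- spec$hyper
  scores <- switch(
    spec$family,
    svm_linear = svm_score(X, y, Xt, kernel = "linear", h),
    svm_poly = svm_score(X, y, Xt, kernel = "polynomial", h),
    svm_rbf = svm_score(X, y, Xt, kernel = "radial", h),
    random_forest = rf_score(X, y, Xt, h),
    lasso = lasso_score(X, y, Xt, h),
    logistic = logistic_score(X, y, Xt, h),
    stepwise_logistic = stepwise_score(X, y, Xt, h))
  if (any(!is.finite(scores))) stop("non-finite scores from ", spec$family)
  unname(scores)
}

svm_score <- function(X, y, Xt, kernel, h) {
  if (ncol(X) == 0) return(rep(0, nrow(Xt)))
  cw <- if (isTRUE(h$class_weight)) {
    tab <- table(factor(y, levels = c(0, 1)))
    stats::setNames(as.numeric(sum(tab) / (2 * tab)), names(tab))
  } else NULL
  fit <- e1071::svm(X, factor(y, levels = c(0, 1)),
                    kernel = kernel,
                    cost = h$cost %||% 1,
                    gamma = h$gamma %||% (1 / ncol(X)),
                    degree = h$degree %||% 3,
                    class.weights = cw, scale = FALSE, probability = FALSE)
  dv <- attr(stats::predict(fit, Xt, decision.values = TRUE),
             "decision.values")
  # e1071 orients the margin toward the first class in colnames "a/b"
  pos_first <- startsWith(colnames(dv)[1], "1/")
  if (pos_first) dv[, 1] else -dv[, 1]
}

rf_score <- function(X, y, Xt, h) {
  if (ncol(X) == 0) return(rep(0, nrow(Xt)))
  mtry <- switch(h$mtry_rule %||% "sqrt",
                 sqrt = max(1, floor(sqrt(ncol(X)))),
                 third = max(1, floor(ncol(X) / 3)))
  fit <- randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                    ntree = h$ntree %||% 500, mtry = mtry)
  stats::predict(fit, Xt, type = "prob")[, "1"]
}

lasso_score <- function(X, y, Xt, h) {
  if (ncol(X) < 2) {
    # glmnet needs >=2 columns; a 1-variable lasso is plain logistic
    return(logistic_score(X, y, Xt, h))
  }
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        standardize = FALSE)
  as.numeric(stats::predict(fit, Xt, s = h$lambda %||% 0.01,
                            type = "link"))
}

# plain logistic scores via glm; aliased coefficients (rank deficiency when
# p >= n) are treated as zero; separation falls back to a ridge fit
logistic_score <- function(X, y, Xt, h) {
  if (ncol(X) == 0) return(rep(0, nrow(Xt)))
  w <- if (isTRUE(h$class_weight)) class_weights(y) else rep(1, length(y))
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(
    tryCatch(stats::glm.fit(Xi, y, weights = w,
                            family = stats::binomial()),
             error = function(e) NULL))
  separated <- is.null(fit) || !fit$converged ||
    any(abs(stats::coef(fit)) > 1e3, na.rm = TRUE)
  if (separated && ncol(X) >= 2) {
    fit_r <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                            lambda = 1e-2, weights = w,
                            standardize = FALSE)
    warning("unstable logistic fit: ridge-stabilized")
    return(as.numeric(stats::predict(fit_r, Xt, type = "link")))
  }
  beta <- stats::coef(fit)
  beta[is.na(beta)] <- 0
  as.numeric(cbind(1, Xt) %*% beta)
}

stepwise_score <- function(X, y, Xt, h) {
  sel <- stepwise_select(X, y, max_steps = h$max_steps %||% 20)
  if (length(sel) == 0) return(rep(0, nrow(Xt)))
  logistic_score(X[, sel, drop = FALSE], y, Xt[, sel, drop = FALSE], h)
}

# weighted logistic deviance via glm.fit; ridge-stabilized IRLS fallback on
# separation/non-convergence so AIC stays comparable
logistic_deviance <- function(Xi, y, w) {
  fit <- suppressWarnings(
    tryCatch(stats::glm.fit(Xi, y, weights = w,
                            family = stats::binomial(),
                            control = list(maxit = 50)),
             error = function(e) NULL))
  if (!is.null(fit) && fit$converged &&
      all(abs(stats::coef(fit)) < 1e3, na.rm = TRUE))
    return(fit$deviance)
  # ridge-stabilized: penalized IRLS with small L2
  beta <- rep(0, ncol(Xi))
  for (it in 1:50) {
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    W <- w * mu * (1 - mu) + 1e-10
    z <- eta + (y - mu) / pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xi, W * Xi) + diag(1e-4, ncol(Xi))
    beta_new <- solve(H, crossprod(Xi, W * z))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  mu <- stats::plogis(drop(Xi %*% beta))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  -2 * sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
}

#' Forward-backward stepwise logistic feature selection
#'
#' Classic hill-climb on a logistic-regression information criterion
#' (AIC = deviance + 2(k+1)): starting from the intercept-only model,
#' repeatedly add the candidate variable that most improves the criterion,
#' then test single removals, stopping when no move strictly improves.
#' Perfect separation during any candidate fit falls back to a
#' ridge-stabilized fit so the criterion stays finite and comparable.
#'
#' @param train_x Numeric matrix or [cohort_table()].
#' @param train_y Labels.
#' @param max_steps Cap on add/remove moves (default 20).
#' @param penalty Criterion penalty per parameter (2 = AIC; `log(n)` gives
#'   BIC).
#' @return Character vector of selected variable names (possibly empty).
#' @export
stepwise_select <- function(train_x, train_y, max_steps = 20, penalty = 2) {
  X <- as_values(train_x)
  y <- as_labels(train_y)
  if (ncol(X) == 0) stop("no candidate variables")
  w <- rep(1, length(y))
  vars <- colnames(X)
  crit <- function(sel) {
    Xi <- cbind(1, X[, sel, drop = FALSE])
    logistic_deviance(Xi, y, w) + penalty * (length(sel) + 1)
  }
  sel <- character()
  best <- crit(sel)
  for (step in seq_len(max_steps)) {
    moved <- FALSE
    # forward
    cand <- setdiff(vars, sel)
    if (length(cand)) {
      cs <- vapply(cand, function(v) crit(c(sel, v)), numeric(1))
      if (min(cs) < best) {
        sel <- c(sel, cand[which.min(cs)])
        best <- min(cs)
        moved <- TRUE
      }
    }
    # backward
    if (length(sel) > 0) {
      ds <- vapply(sel, function(v) crit(setdiff(sel, v)), numeric(1))
      if (min(ds) < best) {
        sel <- setdiff(sel, sel[which.min(ds)])
        best <- min(ds)
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  sel
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen case receives a higher score than
#' a randomly chosen control, with ties counted one half — computed from
#' midranks, which is exactly the normalized Mann-Whitney U statistic.
#' 0.5 corresponds to random assignment; values below 0.5 indicate
#' predictivity toward the wrong class.
#'
#' @param scores Numeric score vector (higher = more case-like).
#' @param labels 0/1 labels or a `target_vector`, both classes present.
#' @return AUC in [0, 1].
#' @export
compute_auc <- function(scores, labels) {
  y <- as_labels(labels)
  if (length(scores) != length(y)) stop("scores/labels length mismatch")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: labels contain a single class")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
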