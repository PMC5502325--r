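# Evaluate expr with a temporary RNG seed, restoring global state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic fan-out of one master seed into per-stage seeds (< 2^31).
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Build a repeated (stratified) cross-validation plan
#'
#' Assigns every subject to exactly one test fold per repeat. With
#' stratification (default), positive subjects are spread so per-fold
#' positive counts differ by at most one and total fold sizes differ by at
#' most one — essential at a 7% case rate, where unstratified 5-fold splits
#' risk positive-free test folds.
#'
#' @param labels 0/1 labels or a `target_vector`.
#' @param n_folds Number of folds N (default 5, i.e. 80/20 splits).
#' @param n_repeats Number of independent repeats (default 30).
#' @param stratified Stratify folds by class (default `TRUE`).
#' @param seed Integer seed; the same seed reproduces the same plan.
#' @return An object of class `cv_plan`: list with `assignments` (an
#'   n_subjects x n_repeats integer matrix of fold ids), `n_folds`,
#'   `n_repeats`, `stratified`, `seed`.
#' @export
make_cv_plan <- function(labels, n_folds = 5, n_repeats = 30,
                         stratified = TRUE, seed = 1) {
  y <- as_labels(labels)
  n <- length(y)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (n_folds > n) stop("more folds than subjects")
  if (stratified && sum(y) < n_folds)
    warning("fewer positives than folds: some test folds will lack cases")
  assignments <- with_seed(seed, {
    vapply(seq_len(n_repeats), function(r) {
      fold <- integer(n)
      resample <- function(x) x[sample.int(length(x))]
      tot <- rep(n %/% n_folds, n_folds)
      if (n %% n_folds) tot[sample.int(n_folds, n %% n_folds)] <- tot[1] + 1
      if (stratified) {
        n1 <- sum(y)
        pos_sz <- rep(n1 %/% n_folds, n_folds)
        if (n1 %% n_folds) {
          big <- order(tot, stats::runif(n_folds), decreasing = TRUE)
          pos_sz[big[seq_len(n1 %% n_folds)]] <- pos_sz[1] + 1
        }
        neg_sz <- tot - pos_sz
        while (any(neg_sz < 0)) {   # pathological prevalence: repair
          i <- which.min(neg_sz); j <- which.max(neg_sz)
          neg_sz[i] <- neg_sz[i] + 1; neg_sz[j] <- neg_sz[j] - 1
        }
        fold[resample(which(y == 1))] <- rep(seq_len(n_folds), pos_sz)
        fold[resample(which(y == 0))] <- rep(seq_len(n_folds), neg_sz)
      } else {
        fold[sample.int(n)] <- rep(seq_len(n_folds), tot)
      }
      fold
    }, integer(n))
  })
  structure(list(assignments = assignments, n_folds = n_folds,
                 n_repeats = n_repeats, stratified = stratified,
                 seed = seed),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("cv_plan: %d subjects, %d folds x %d repeats (%s), seed %d\n",
              nrow(x$assignments), x$n_folds, x$n_repeats,
              if (x$stratified) "stratified" else "unstratified", x$seed))
  invisible(x)
}

#' Inner-loop model selection
#'
#' Evaluates every grid point by cross-validation *within* the outer
#' training set (N-1 folds by default), pooling held-out scores across
#' inner folds into one AUC per grid point, and returns the winner. Ties
#' break to the earlier grid entry, so selection is deterministic.
#'
#' @param train_x Complete, normalized training table/matrix.
#' @param train_y Training labels.
#' @param grid List of [model_spec()]s.
#' @param n_folds Inner fold count (default 4).
#' @param seed Seed for the inner fold assignment.
#' @return List with `spec` (winning `model_spec`) and `inner_auc`.
#' @export
inner_select <- function(train_x, train_y, grid, n_folds = 4, seed = 1) {
  y <- as_labels(train_y)
  if (length(grid) == 1)
    return(list(spec = grid[[1]], inner_auc = NA_real_))
  plan <- make_cv_plan(y, n_folds = n_folds, n_repeats = 1,
                       stratified = TRUE, seed = seed)
  fold <- plan$assignments[, 1]
  X <- as_values(train_x)
  # lasso grids varying only in lambda: one glmnet path per fold scores
  # every grid point, instead of refitting per lambda
  # pooled AUC over the inner folds that produced scores; an inner fold
  # whose training data cannot support a fit (e.g. single-class at very
  # low prevalence) is skipped rather than failing the grid point
  pooled_auc <- function(sc) {
    obs <- !is.na(sc)
    if (!any(obs) || length(unique(y[obs])) < 2) return(-Inf)
    compute_auc(sc[obs], y[obs])
  }
  fams <- vapply(grid, `[[`, character(1), "family")
  if (all(fams == "lasso") && ncol(X) >= 2) {
    # lasso grids varying only in lambda: one glmnet path per fold scores
    # every grid point, instead of refitting per lambda
    lambdas <- vapply(grid, function(g) g$hyper$lambda, numeric(1))
    sc <- matrix(NA_real_, length(y), length(grid))
    for (f in seq_len(n_folds)) {
      tr <- fold != f; te <- fold == f
      s <- tryCatch({
        fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                              family = "binomial", alpha = 1,
                              standardize = FALSE)
        stats::predict(fit, X[te, , drop = FALSE], s = lambdas,
                       type = "link")
      }, error = function(e) NULL)
      if (!is.null(s)) sc[te, ] <- s
    }
    aucs <- apply(sc, 2, pooled_auc)
    if (any(is.finite(aucs))) {
      win <- which.max(aucs)
      return(list(spec = grid[[win]], inner_auc = aucs[win]))
    }
  }
  aucs <- vapply(grid, function(spec) {
    sc <- rep(NA_real_, length(y))
    for (f in seq_len(n_folds)) {
      tr <- fold != f; te <- fold == f
      s <- tryCatch(
        fit_score(spec, X[tr, , drop = FALSE], y[tr], X[te, , drop = FALSE]),
        error = function(e) NULL)
      if (!is.null(s)) sc[te] <- s
    }
    pooled_auc(sc)
  }, numeric(1))
  if (all(!is.finite(aucs))) {
    # no inner split could score any grid point (e.g. too few positives to
    # stratify the inner folds): fall back to the first grid entry
    fail <- vapply(grid, function(spec)
      is.null(tryCatch(fit_score(spec, X, y, X[1, , drop = FALSE]),
                       error = function(e) NULL)), logical(1))
    if (all(fail)) stop("all grid points failed to fit")
    warning("inner selection unscoreable: using the first fittable grid entry")
    return(list(spec = grid[[which(!fail)[1]]], inner_auc = NA_real_))
  }
  win <- which.max(aucs)     # first maximum: deterministic tie-break
  list(spec = grid[[win]], inner_auc = aucs[win])
}

#' Repeated nested N-fold cross-validation
#'
#' The error-estimation protocol: an outer loop holds out each fold once
#' per repeat; inside each outer training set an inner loop (N-1 folds)
#' selects the hyperparameters; the winner is refit on the whole training
#' set and scores the held-out fold. Because no model ever saw its test
#' subjects — preprocessing statistics (imputation donors, normalization
#' bounds) and feature selection are computed inside each outer training
#' set — the outer AUCs are unbiased. Held-out scores are pooled over the
#' folds of a repeat into one AUC per repeat (stable even with 2-3
#' positives per fold), and the mean and SD are taken across repeats.
#'
#' @param table A [cohort_table()]; may contain missing values (the
#'   missingness filter is applied once, then imputation/normalization are
#'   refit per outer fold).
#' @param target Labels (`target_vector` or 0/1 vector).
#' @param families Named list of grids as from [default_family_grids()].
#' @param feature_selection `"none"`, `"hiton"` (HITON-PC run inside each
#'   outer training fold), or `"hiton_full"` — a deliberately *leaky* mode
#'   that selects once on the full data before CV, provided only to
#'   demonstrate the selection-bias inflation the fold-internal protocol
#'   avoids.
#' @param hiton_params List of HITON-PC parameters (`alpha`, `max_k`,
#'   `ci_test`).
#' @param plan A [make_cv_plan()] object, or `NULL` to build one from
#'   `n_folds` / `n_repeats` / `seed`.
#' @param n_folds,n_repeats,seed Used when `plan` is `NULL`; seed also
#'   drives inner folds and stochastic learners.
#' @param missingness_threshold,impute_k Preprocessing controls.
#' @param preprocess Set `FALSE` when `table` is already complete and
#'   normalized (e.g. simulation studies without missingness); fold-wise
#'   imputation/normalization is then skipped.
#' @param auc_aggregation How held-out scores of one repeat become one AUC.
#'   `"pooled_rank"` (default) pools all held-out subjects after mapping
#'   each fold's scores to normalized within-fold ranks, which makes scores
#'   comparable across fold models; its null expectation is exactly 0.5 by
#'   exchangeability. `"pooled"` pools raw scores (scale shifts between
#'   fold models make this measurably pessimistic under the null).
#'   `"per_fold"` averages per-fold AUCs over folds containing both
#'   classes (unstable with only 2-3 positives per fold).
#' @return Object of class `rnncv_result`: per family a
#'   `performance_estimate` (fields `per_repeat_auc`, `mean_auc`, `sd_auc`,
#'   `chosen_specs`, `selected_features`), plus the plan.
#' @export
run_rnncv <- function(table, target,
                      families = default_family_grids(),
                      feature_selection = c("none", "hiton", "hiton_full"),
                      hiton_params = list(alpha = 0.05, max_k = 3,
                                          ci_test = "fisher_z"),
                      plan = NULL, n_folds = 5, n_repeats = 30, seed = 1,
                      missingness_threshold = 0.5, impute_k = 10,
                      preprocess = TRUE,
                      auc_aggregation = c("pooled_rank", "pooled",
                                          "per_fold")) {
  feature_selection <- match.arg(feature_selection)
  auc_aggregation <- match.arg(auc_aggregation)
  y <- as_labels(target)
  if (inherits(table, "cohort_table") && preprocess)
    table <- drop_high_missingness(table, missingness_threshold)$table
  if (is.null(plan))
    # hash the seed so a caller reusing one integer for data generation
    # and for the protocol cannot alias the two RNG streams
    plan <- make_cv_plan(y, n_folds = n_folds, n_repeats = n_repeats,
                         stratified = TRUE,
                         seed = derive_seed(seed, "cvplan"))
  n_repeats <- plan$n_repeats; n_folds <- plan$n_folds
  tbl <- if (inherits(table, "cohort_table")) table
         else cohort_table(as.matrix(table))
  if (!preprocess && any(tbl$missing))
    stop("preprocess = FALSE but table has missing values")

  leak_pc <- NULL
  if (feature_selection == "hiton_full") {
    full <- if (preprocess)
      preprocess_cohort(tbl, missingness_threshold, impute_k)$table
    else tbl
    leak_pc <- select_within_fold(full, y, hiton_params)$selected
  }

  fam_names <- names(families)
  per_repeat <- matrix(NA_real_, n_repeats, length(fam_names),
                       dimnames = list(NULL, fam_names))
  chosen <- vector("list", length(fam_names)); names(chosen) <- fam_names
  selected_features <- list()

  for (r in seq_len(n_repeats)) {
    fold <- plan$assignments[, r]
    scores <- matrix(NA_real_, length(y), length(fam_names),
                     dimnames = list(NULL, fam_names))
    for (f in seq_len(n_folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      if (preprocess) {
        tr_tbl <- knn_impute(tbl[tr, ], k = impute_k)
        te_tbl <- knn_impute(tbl[te, ], k = impute_k, donors = tr_tbl)
        nrm <- suppressWarnings(minmax_normalize(tr_tbl))
        Xtr <- nrm$table$values
        Xte <- apply_normalization(te_tbl, nrm$bounds)$values
      } else {
        Xtr <- tbl$values[tr, , drop = FALSE]
        Xte <- tbl$values[te, , drop = FALSE]
      }
      feats <- colnames(Xtr)
      if (feature_selection == "hiton") {
        pc <- suppressWarnings(select_within_fold(
          cohort_table(Xtr, kinds = unname(tbl$kinds[feats])),
          y[tr], hiton_params))
        feats <- pc$selected
        selected_features[[sprintf("r%d_f%d", r, f)]] <- feats
      } else if (feature_selection == "hiton_full") {
        feats <- leak_pc
      }
      Xtr_f <- Xtr[, feats, drop = FALSE]
      Xte_f <- Xte[, feats, drop = FALSE]
      for (fam in fam_names) {
        s_inner <- derive_seed(plan$seed, r, f, fam)
        pick <- with_seed(s_inner,
          inner_select(Xtr_f, y[tr], families[[fam]],
                       n_folds = max(2, n_folds - 1), seed = s_inner))
        scores[te, fam] <- with_seed(derive_seed(s_inner, "fit"),
          fit_score(pick$spec, Xtr_f, y[tr], Xte_f))
        chosen[[fam]][[sprintf("r%d_f%d", r, f)]] <- pick$spec
      }
    }
    for (fam in fam_names)
      per_repeat[r, fam] <- aggregate_auc(scores[, fam], y, fold,
                                          auc_aggregation)
  }

  estimates <- lapply(fam_names, function(fam) {
    structure(list(per_repeat_auc = per_repeat[, fam],
                   mean_auc = mean(per_repeat[, fam]),
                   sd_auc = stats::sd(per_repeat[, fam]),
                   chosen_specs = chosen[[fam]],
                   family = fam),
              class = "performance_estimate")
  })
  names(estimates) <- fam_names
  structure(list(estimates = estimates, plan = plan,
                 auc_aggregation = auc_aggregation,
                 feature_selection = feature_selection,
                 selected_features = selected_features),
            class = "rnncv_result")
}

# one AUC for a repeat's held-out scores; see run_rnncv(auc_aggregation=)
aggregate_auc <- function(sc, y, fold, method) {
  switch(method,
    pooled = compute_auc(sc, y),
    pooled_rank = {
      rnk <- stats::ave(sc, fold,
                        FUN = function(v) rank(v) / (length(v) + 1))
      compute_auc(rnk, y)
    },
    per_fold = {
      aucs <- vapply(unique(fold), function(f) {
        yt <- y[fold == f]
        if (length(unique(yt)) < 2) return(NA_real_)
        compute_auc(sc[fold == f], yt)
      }, numeric(1))
      if (all(is.na(aucs)))
        stop("no fold contains both classes: cannot average per-fold AUC")
      mean(aucs, na.rm = TRUE)
    })
}

#' @export
print.performance_estimate <- function(x, ...) {
  cat(sprintf("%s: mean AUC %.3f (SD %.3f) over %d repeats\n",
              x$family, x$mean_auc,
              if (is.na(x$sd_auc)) 0 else x$sd_auc,
              length(x$per_repeat_auc)))
  invisible(x)
}

#' @export
print.rnncv_result <- function(x, ...) {
  cat(sprintf("rnncv_result (feature selection: %s)\n",
              x$feature_selection))
  for (e in x$estimates) print(e)
  invisible(x)
}

#' Summarize an RNNCV result as a table
#' @param object An `rnncv_result`.
#' @param ... Ignored.
#' @return data.frame with family, mean_auc, sd_auc.
#' @export
summary.rnncv_result <- function(object, ...) {
  data.frame(
    family = names(object$estimates),
    mean_auc = vapply(object$estimates, `[[`, numeric(1), "mean_auc"),
    sd_auc = vapply(object$estimates, `[[`, numeric(1), "sd_auc"),
    row.names = NULL, stringsAsFactors = FALSE)
}
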