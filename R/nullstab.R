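#' Label-shuffling permutation test for overall predictive signal
#'
#' Reruns the full RNNCV protocol — identical families, grids,
#' feature-selection placement and preprocessing — on data sets whose
#' outcome labels have been uniformly permuted. The null distribution of
#' mean AUCs serves two purposes: its mean diagnoses protocol bias (an
#' unbiased protocol gives 0.5 under the null; any departure measures the
#' bias), and its upper tail gives a one-sided p-value for the observed
#' AUC. The p-value uses the add-one estimator
#' p = (1 + #\{null >= observed\}) / (1 + n_permutations), so it is never
#' exactly zero.
#'
#' Each permutation may rerun the protocol with fewer outer repeats than
#' the observed analysis (default 5): the null *mean* is invariant to the
#' repeat count, and the saving makes hundreds of permutations tractable;
#' set `null_repeats` equal to the observed repeats for full fidelity.
#'
#' @param table A [cohort_table()].
#' @param target Observed labels.
#' @param observed_auc Mean AUC of the observed-data run being tested (for
#'   one family); may be `NA` to obtain the null distribution only.
#' @param families Grid list for the protocol (typically one family).
#' @param feature_selection,hiton_params As in [run_rnncv()].
#' @param n_permutations Number of label shuffles (default 400; fewer than
#'   20 triggers a resolution warning).
#' @param null_repeats Outer repeats per permutation run (default 5).
#' @param n_folds Outer folds (default 5).
#' @param seed Master seed; permutation p and fold seeds derive from it.
#' @param preprocess Passed to [run_rnncv()].
#' @return Object of class `permutation_result`: `observed_auc`,
#'   `null_aucs`, `null_mean`, `null_ci95`, `p_one_sided`.
#' @export
label_shuffle_test <- function(table, target, observed_auc = NA_real_,
                               families = default_family_grids("lasso"),
                               feature_selection = "none",
                               hiton_params = list(alpha = 0.05, max_k = 3,
                                                   ci_test = "fisher_z"),
                               n_permutations = 400, null_repeats = 5,
                               n_folds = 5, seed = 1, preprocess = TRUE) {
  if (n_permutations < 20)
    warning("fewer than 20 permutations: p-value resolution is coarse")
  y <- as_labels(target)
  null_aucs <- vapply(seq_len(n_permutations), function(b) {
    y_perm <- with_seed(derive_seed(seed, "perm", b), sample(y))
    res <- run_rnncv(table, y_perm, families = families,
                     feature_selection = feature_selection,
                     hiton_params = hiton_params,
                     n_folds = n_folds, n_repeats = null_repeats,
                     seed = derive_seed(seed, "protocol", b),
                     preprocess = preprocess)
    mean(vapply(res$estimates, `[[`, numeric(1), "mean_auc"))
  }, numeric(1))
  structure(
    list(observed_auc = observed_auc,
         null_aucs = null_aucs,
         null_mean = mean(null_aucs),
         null_ci95 = unname(stats::quantile(null_aucs, c(0.025, 0.975))),
         p_one_sided = if (is.na(observed_auc)) NA_real_
                       else (1 + sum(null_aucs >= observed_auc)) /
                            (1 + n_permutations),
         n_permutations = n_permutations),
    class = "permutation_result")
}

#' Add-one permutation p-value
#'
#' @param observed Observed statistic.
#' @param null_values Vector of null statistics.
#' @return (1 + #\{null >= observed\}) / (1 + length(null_values)).
#' @export
permutation_p <- function(observed, null_values) {
  (1 + sum(null_values >= observed)) / (1 + length(null_values))
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: null mean %.3f [%.3f, %.3f] over %d shuffles\n",
    x$null_mean, x$null_ci95[1], x$null_ci95[2], x$n_permutations))
  if (!is.na(x$observed_auc))
    cat(sprintf("  observed AUC %.3f, one-sided p = %.4g\n",
                x$observed_auc, x$p_one_sided))
  invisible(x)
}

#' Bootstrap stability of HITON-PC selections
#'
#' Draws B bootstrap resamples of the subjects (with replacement, size n),
#' reruns HITON-PC on each — after fold-free imputation and normalization
#' of the resample — and counts how often every variable is selected.
#' Variables selected in strictly more than `threshold_count` resamples
#' form the stable set. Resamples are stratified by class by default
#' (resampling within cases and controls separately) so that no resample
#' is single-class at a rare-outcome prevalence; an unstratified resample
#' that comes out single-class is redrawn and logged.
#'
#' @param table A [cohort_table()].
#' @param target Labels.
#' @param hiton_params List of HITON-PC parameters.
#' @param B Number of bootstrap resamples (default 100).
#' @param threshold_count Strict count threshold for the stable set
#'   (default 20, i.e. "selected in more than 20 of 100").
#' @param stratified Stratify resamples by class (default `TRUE`).
#' @param seed Master seed.
#' @param missingness_threshold,impute_k Preprocessing controls.
#' @param preprocess Set `FALSE` for complete, normalized input.
#' @return Object of class `stability_profile`: `frequencies` (named
#'   integer vector over all variables), `B`, `threshold_count`,
#'   `stable_set`, `per_resample` (list of selected sets).
#' @export
bootstrap_stability <- function(table, target,
                                hiton_params = list(alpha = 0.05, max_k = 3,
                                                    ci_test = "fisher_z"),
                                B = 100, threshold_count = 20,
                                stratified = TRUE, seed = 1,
                                missingness_threshold = 0.5, impute_k = 10,
                                preprocess = TRUE) {
  stopifnot(B >= 1)
  y <- as_labels(target)
  tbl <- if (inherits(table, "cohort_table")) table
         else cohort_table(as.matrix(table))
  if (preprocess)
    tbl <- drop_high_missingness(tbl, missingness_threshold)$table
  vars <- variable_names(tbl)
  freq <- stats::setNames(integer(length(vars)), vars)
  per_resample <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- with_seed(derive_seed(seed, "boot", b), {
      if (stratified) {
        pos <- which(y == 1); neg <- which(y == 0)
        c(pos[sample.int(length(pos), length(pos), replace = TRUE)],
          neg[sample.int(length(neg), length(neg), replace = TRUE)])
      } else {
        repeat {
          i <- sample.int(length(y), replace = TRUE)
          if (length(unique(y[i])) == 2) break
          message("single-class resample redrawn (b = ", b, ")")
        }
        i
      }
    })
    sub <- tbl[idx, ]
    if (preprocess) {
      sub <- knn_impute(sub, k = impute_k)
      sub <- suppressWarnings(minmax_normalize(sub))$table
    }
    pc <- suppressWarnings(select_within_fold(sub, y[idx], hiton_params))
    per_resample[[b]] <- pc$selected
    freq[pc$selected] <- freq[pc$selected] + 1L
  }
  structure(list(frequencies = freq, B = B,
                 threshold_count = threshold_count,
                 stable_set = names(freq)[freq > threshold_count],
                 per_resample = per_resample,
                 params = hiton_params),
            class = "stability_profile")
}

#' @export
print.stability_profile <- function(x, ...) {
  cat(sprintf(
    "stability_profile: %d bootstraps, %d variables ever selected, %d stable (> %d)\n",
    x$B, sum(x$frequencies > 0), length(x$stable_set), x$threshold_count))
  invisible(x)
}

#' Rank variables by bootstrap selection frequency
#'
#' @param profile A `stability_profile`.
#' @param all Include variables never selected (default `FALSE`).
#' @return data.frame with `variable`, `frequency`, `stable`, ordered by
#'   descending frequency with lexicographic tie-break.
#' @export
rank_stable <- function(profile, all = FALSE) {
  f <- profile$frequencies
  if (!all) f <- f[f > 0]
  ord <- order(-f, names(f))
  data.frame(variable = names(f)[ord],
             frequency = unname(f[ord]),
             stable = unname(f[ord]) > profile$threshold_count,
             row.names = NULL, stringsAsFactors = FALSE)
}
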