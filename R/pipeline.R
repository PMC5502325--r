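#' Default pipeline configuration
#'
#' One list with a section per stage, every value overridable. The master
#' `seed` fans out deterministically to the CV plans, permutations,
#' bootstraps and stochastic learners of each stage.
#'
#' @param ... Named overrides of any default.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    families = c("svm_linear", "svm_poly", "svm_rbf", "random_forest",
                 "lasso", "logistic", "stepwise_logistic"),
    reduced_grids = FALSE,
    missingness_threshold = 0.5,
    impute_k = 10,
    alpha = 0.05,
    max_k = 3,
    ci_test = "fisher_z",
    n_folds = 5,
    n_repeats = 30,
    n_permutations = 400,
    null_repeats = 5,
    n_bootstraps = 100,
    stability_threshold = 20,
    seed = 1)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

stars_for <- function(p) {
  if (is.na(p)) "" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Run the complete analysis pipeline
#'
#' One-command reproduction driver: preprocessing (missingness filter,
#' fold-wise imputation and normalization), repeated nested cross-validated
#' AUC estimation for every configured classifier family both with all
#' features and with fold-internal HITON-PC selection, label-shuffling
#' significance testing of each cell, and bootstrap stability ranking of
#' the selected variables. Emits a classifier-by-selection performance
#' table with significance stars (* p < 0.05, ** p < 0.01 from the
#' one-sided permutation p), a stability frequency table, and a run
#' manifest (config snapshot, seeds, timings, output checksums).
#'
#' @param table A [cohort_table()].
#' @param target Labels.
#' @param config List from [default_config()].
#' @param out_dir Optional directory for TSV/JSON outputs.
#' @param quiet Suppress progress messages.
#' @return List of class `mbrisk_run`: `performance` (data.frame, one row
#'   per family x feature-selection cell), `stability` (frequency table),
#'   `rnncv` (raw results), `manifest`.
#' @export
run_full_analysis <- function(table, target, config = default_config(),
                              out_dir = NULL, quiet = FALSE) {
  t0 <- Sys.time()
  y <- as_labels(target)
  say <- function(...) if (!quiet) message(sprintf(...))
  say("cohort: %d subjects, %d variables, %d positives (%.1f%%)",
      nrow(table$values), ncol(table$values), sum(y), 100 * mean(y))

  filt <- drop_high_missingness(table, config$missingness_threshold)
  say("missingness filter: %d variables dropped, %d retained",
      nrow(filt$report$dropped_variables), ncol(filt$table$values))

  grids <- default_family_grids(config$families,
                                reduced = config$reduced_grids)
  hiton_params <- list(alpha = config$alpha, max_k = config$max_k,
                       ci_test = config$ci_test)
  timings <- list(preprocess = as.numeric(Sys.time() - t0, units = "secs"))

  rnncv_res <- list(); perf_rows <- list()
  for (fsel in c("none", "hiton")) {
    t1 <- Sys.time()
    say("RNNCV (%s): %d repeats x %d folds, %d families",
        fsel, config$n_repeats, config$n_folds, length(grids))
    res <- run_rnncv(filt$table, y, families = grids,
                     feature_selection = fsel,
                     hiton_params = hiton_params,
                     n_folds = config$n_folds,
                     n_repeats = config$n_repeats,
                     seed = derive_seed(config$seed, "rnncv", fsel),
                     missingness_threshold = config$missingness_threshold,
                     impute_k = config$impute_k)
    rnncv_res[[fsel]] <- res
    timings[[paste0("rnncv_", fsel)]] <-
      as.numeric(Sys.time() - t1, units = "secs")

    for (fam in names(grids)) {
      t2 <- Sys.time()
      est <- res$estimates[[fam]]
      perm <- label_shuffle_test(
        filt$table, y, observed_auc = est$mean_auc,
        families = grids[fam], feature_selection = fsel,
        hiton_params = hiton_params,
        n_permutations = config$n_permutations,
        null_repeats = config$null_repeats,
        n_folds = config$n_folds,
        seed = derive_seed(config$seed, "perm", fsel, fam))
      perf_rows[[paste(fam, fsel)]] <- data.frame(
        family = fam, feature_selection = fsel,
        mean_auc = est$mean_auc, sd_auc = est$sd_auc,
        null_mean = perm$null_mean,
        null_lo = perm$null_ci95[1], null_hi = perm$null_ci95[2],
        p_one_sided = perm$p_one_sided,
        stars = stars_for(perm$p_one_sided),
        stringsAsFactors = FALSE)
      timings[[paste0("perm_", fam, "_", fsel)]] <-
        as.numeric(Sys.time() - t2, units = "secs")
      say("  %s / %s: AUC %.3f (%.3f) null %.3f p=%.3g %s",
          fam, fsel, est$mean_auc, est$sd_auc, perm$null_mean,
          perm$p_one_sided, stars_for(perm$p_one_sided))
    }
  }

  t3 <- Sys.time()
  say("bootstrap stability: %d resamples", config$n_bootstraps)
  stab <- bootstrap_stability(
    filt$table, y, hiton_params = hiton_params,
    B = config$n_bootstraps,
    threshold_count = config$stability_threshold,
    seed = derive_seed(config$seed, "stability"),
    missingness_threshold = config$missingness_threshold,
    impute_k = config$impute_k)
  timings$stability <- as.numeric(Sys.time() - t3, units = "secs")

  performance <- do.call(rbind, perf_rows)
  rownames(performance) <- NULL
  out <- list(performance = performance,
              stability = rank_stable(stab),
              stability_profile = stab,
              rnncv = rnncv_res,
              config = config)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f1 <- file.path(out_dir, "performance.tsv")
    utils::write.table(performance, f1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f2 <- file.path(out_dir, "stability.tsv")
    utils::write.table(out$stability, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(f1, f2)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("mbrisk")),
    config = config, seed = config$seed,
    n_subjects = nrow(table$values), n_variables = ncol(table$values),
    n_variables_after_filter = ncol(filt$table$values),
    n_positives = sum(y),
    timings_sec = timings,
    outputs = if (length(files))
      as.list(tools::md5sum(files)) else list())
  out$manifest <- manifest
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  class(out) <- "mbrisk_run"
  out
}

#' @export
print.mbrisk_run <- function(x, ...) {
  cat("mbrisk_run\n")
  print(x$performance[, c("family", "feature_selection", "mean_auc",
                          "sd_auc", "null_mean", "p_one_sided", "stars")])
  cat(sprintf("stable variables (> %d of %d bootstraps): %s\n",
              x$stability_profile$threshold_count,
              x$stability_profile$B,
              paste(x$stability_profile$stable_set, collapse = ", ")))
  invisible(x)
}
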