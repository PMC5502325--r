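#' Drop variables with excessive missingness
#'
#' Removes every variable whose fraction of missing entries is strictly
#' greater than `threshold` (default 0.5, i.e. "missing greater than 50% of
#' subject data"). A variable missing exactly the threshold fraction is
#' retained. The filter uses no outcome information, so it is applied once
#' to the full data set without leakage.
#'
#' @param table A [cohort_table()].
#' @param threshold Missing fraction above which a variable is dropped.
#' @return List with `table` (the filtered cohort) and `report`, a
#'   `preprocess_report` holding `dropped_variables` (name, missing
#'   fraction) for each removed variable.
#' @export
drop_high_missingness <- function(table, threshold = 0.5) {
  frac <- colMeans(table$missing)
  drop <- frac > threshold
  if (all(drop))
    stop("all variables exceed the missingness threshold")
  report <- structure(
    list(dropped_variables = data.frame(
           variable = variable_names(table)[drop],
           missing_fraction = unname(frac[drop]),
           stringsAsFactors = FALSE),
         threshold = threshold),
    class = "preprocess_report")
  list(table = table[, !drop], report = report)
}

#' Unsupervised k-nearest-neighbour imputation
#'
#' Fills each missing cell with the plain (unweighted) mean of that variable
#' over the k nearest donor subjects, where distance is Euclidean over the
#' coordinates observed in both subjects, scaled by the number of shared
#' coordinates. Donors must have the variable observed. The outcome label is
#' never an input: imputation is strictly unsupervised. Imputed values for
#' binary and categorical variables are rounded to the nearest observed
#' level so that discrete-data tests downstream stay valid.
#'
#' @param table A [cohort_table()] whose rows need imputing.
#' @param k Number of donor neighbours (default 10). Clamped to the number
#'   of available donors with a warning when too large.
#' @param donors Optional `cohort_table` providing the donor pool (e.g. the
#'   training fold when imputing held-out subjects). Defaults to `table`
#'   itself.
#' @param weighting `"uniform"` (default, plain mean) or
#'   `"inverse-distance"`.
#' @return The imputed `cohort_table` (missing mask all `FALSE`).
#' @export
knn_impute <- function(table, k = 10, donors = NULL,
                       weighting = c("uniform", "inverse-distance")) {
  weighting <- match.arg(weighting)
  self_donor <- is.null(donors)
  if (self_donor) donors <- table
  X <- table$values
  D <- donors$values
  if (!identical(colnames(X), colnames(D)))
    stop("donor variables do not match")
  if (any(rowSums(!table$missing) == 0))
    stop("subject with zero observed values cannot be imputed")
  if (any(colSums(!donors$missing) == 0))
    stop("variable with zero observed donor values cannot be imputed")
  if (!any(table$missing)) return(table)

  Dobs <- !donors$missing
  D0 <- D; D0[!Dobs] <- 0
  out <- X
  need <- which(rowSums(table$missing) > 0)
  for (i in need) {
    xi <- X[i, ]
    oi <- !table$missing[i, ]
    # squared distance over mutually observed coords, normalized by overlap
    xi0 <- ifelse(oi, xi, 0)
    shared <- Dobs %*% oi                       # overlap count per donor
    cross <- D0 %*% xi0
    di2 <- (D0^2) %*% oi + Dobs %*% (xi0^2) - 2 * cross
    d2 <- ifelse(shared > 0, di2 / shared, Inf)
    if (self_donor) d2[i] <- Inf
    miss_j <- which(table$missing[i, ])
    for (j in miss_j) {
      cand <- which(Dobs[, j] & is.finite(d2))
      if (length(cand) == 0)
        stop("no donor observes variable ", colnames(X)[j])
      kk <- k
      if (kk > length(cand)) {
        warning("k clamped to ", length(cand), " available donors")
        kk <- length(cand)
      }
      nn <- cand[order(d2[cand], cand)[seq_len(kk)]]
      if (weighting == "uniform") {
        val <- mean(D[nn, j])
      } else {
        w <- 1 / pmax(sqrt(d2[nn]), 1e-12)
        val <- sum(w * D[nn, j]) / sum(w)
      }
      if (table$kinds[j] %in% c("binary", "categorical")) {
        levs <- sort(unique(D[Dobs[, j], j]))
        val <- levs[which.min(abs(levs - val))]
      }
      out[i, j] <- val
    }
  }
  cohort_table(out, kinds = unname(table$kinds),
               subject_ids = table$subject_ids)
}

#' Min-max normalization to the unit interval
#'
#' Maps each variable by (x - min) / (max - min) so every training value
#' lies in [0, 1], reducing artifacts due to differences in scaling.
#' Constant variables map to all zeros with a warning. The learned bounds
#' can be applied to held-out data with [apply_normalization()]; held-out
#' values outside the training range are deliberately not clipped, so they
#' may fall outside [0, 1].
#'
#' @param table A complete (imputed) [cohort_table()].
#' @return List with `table` (normalized cohort) and `bounds`, a two-row
#'   matrix (`min`, `max`) per variable.
#' @export
minmax_normalize <- function(table) {
  if (any(table$missing)) stop("normalize after imputation: missing values present")
  X <- table$values
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  if (any(hi == lo))
    warning("constant variable(s) mapped to zero: ",
            paste(colnames(X)[hi == lo], collapse = ", "))
  bounds <- rbind(min = lo, max = hi)
  list(table = apply_normalization(table, bounds), bounds = bounds)
}

#' Apply stored normalization bounds
#'
#' @param table A complete [cohort_table()].
#' @param bounds Bounds matrix from [minmax_normalize()].
#' @return Normalized `cohort_table` (values outside the training range are
#'   not clipped).
#' @export
apply_normalization <- function(table, bounds) {
  X <- table$values
  lo <- bounds["min", colnames(X)]
  hi <- bounds["max", colnames(X)]
  rng <- hi - lo
  rng[rng == 0] <- 1           # constant columns map to 0
  Xn <- sweep(sweep(X, 2, lo, "-"), 2, rng, "/")
  cohort_table(Xn, kinds = unname(table$kinds),
               subject_ids = table$subject_ids)
}

#' Full preprocessing pipeline: filter, impute, normalize
#'
#' Convenience wrapper running [drop_high_missingness()], [knn_impute()] and
#' [minmax_normalize()] in the canonical order on a whole cohort. Inside
#' cross-validation, use the component functions with training-fold donors
#' and bounds instead (see [run_rnncv()]).
#'
#' @param table A [cohort_table()].
#' @param missingness_threshold Passed to [drop_high_missingness()].
#' @param impute_k Passed to [knn_impute()].
#' @param weighting Passed to [knn_impute()].
#' @return List with `table` (ready for analysis), `report` (dropped
#'   variables and imputed cell count), `bounds`.
#' @export
preprocess_cohort <- function(table, missingness_threshold = 0.5,
                              impute_k = 10, weighting = "uniform") {
  f <- drop_high_missingness(table, missingness_threshold)
  n_imputed <- sum(f$table$missing)
  imp <- knn_impute(f$table, k = impute_k, weighting = weighting)
  nrm <- minmax_normalize(imp)
  rep <- f$report
  rep$imputed_cell_count <- n_imputed
  rep$normalization_bounds <- nrm$bounds
  list(table = nrm$table, report = rep, bounds = nrm$bounds)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("preprocess_report: %d variables dropped (missing > %g)\n",
              nrow(x$dropped_variables), x$threshold))
  if (!is.null(x$imputed_cell_count))
    cat(sprintf("  %d cells imputed\n", x$imputed_cell_count))
  invisible(x)
}
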