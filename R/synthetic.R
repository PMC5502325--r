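#' Specification of a synthetic cohort
#'
#' Describes a cohort with the statistical structure the analysis pipeline
#' assumes: a small set of planted "parent" variables driving a rare binary
#' target through a logistic link, correlated distractors that are noisy
#' copies of parents (information overlap), independent noise variables of
#' mixed kinds, and missing-completely-at-random entries including a few
#' columns pushed above 50% missingness. Defaults emulate an acute-injury
#' child cohort: 163 subjects, 105 predictors, 7% prevalence, and parent
#' effects sized so the Bayes-optimal AUC is about 0.80.
#'
#' Distractors are noisy copies of parents rather than children of the
#' target: with a terminal target the PC set equals the parent set, giving
#' clean ground truth for recovery tests.
#'
#' @param n_subjects,n_variables Cohort dimensions (defaults 163, 105).
#' @param n_parents Number of planted direct causes (default 5).
#' @param parent_effects Log-odds effect per standardized parent (default
#'   0.57 each, calibrated for Bayes AUC about 0.80 at 7% prevalence).
#' @param target_prevalence Marginal case probability (default 0.07).
#' @param n_correlated_distractors Noisy parent copies (default 10).
#' @param distractor_correlation Correlation of a distractor with its
#'   parent (default 0.6).
#' @param kind_mix Named fractions of binary/categorical/continuous
#'   variables (default 0.4/0.2/0.4).
#' @param missing_rate MCAR cell missingness over predictors (default
#'   0.05).
#' @param high_missing_columns Noise columns forced to about 60%
#'   missingness, i.e. above the 50% filter (default 3).
#' @param seed Integer seed; identical specs generate identical cohorts.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 163, n_variables = 105,
                           n_parents = 5,
                           parent_effects = rep(0.57, n_parents),
                           target_prevalence = 0.07,
                           n_correlated_distractors = 10,
                           distractor_correlation = 0.6,
                           kind_mix = c(binary = 0.4, categorical = 0.2,
                                        continuous = 0.4),
                           missing_rate = 0.05,
                           high_missing_columns = 3,
                           seed = 1) {
  stopifnot(n_parents + n_correlated_distractors <= n_variables,
            target_prevalence > 0, target_prevalence < 1,
            all(is.finite(parent_effects)),
            length(parent_effects) == n_parents,
            distractor_correlation > 0, distractor_correlation < 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

# draw n values of a variable of the given kind; standardized version has
# mean 0 sd 1 using theoretical moments
draw_kind <- function(kind, n) {
  switch(kind,
         binary = stats::rbinom(n, 1, 0.5),
         categorical = sample(0:4, n, replace = TRUE),
         continuous = stats::rnorm(n))
}

standardize_kind <- function(v, kind) {
  switch(kind,
         binary = (v - 0.5) / 0.5,
         categorical = (v - 2) / sqrt(2),
         continuous = v)
}

# intercept b0 with E[plogis(b0 + s)] = prevalence, by root-finding on a
# fixed Monte-Carlo draw of the linear predictor (tolerance < 0.002)
solve_intercept <- function(draw_s, prevalence, n_mc = 2e5) {
  s <- draw_s(n_mc)
  if (all(s == 0)) return(stats::qlogis(prevalence))
  f <- function(b) mean(stats::plogis(b + s)) - prevalence
  lo <- -30; hi <- 10
  if (f(lo) > 0 || f(hi) < 0)
    stop("unsolvable prevalence: parent effects too extreme")
  stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
}

#' Generate a synthetic cohort with known causal ground truth
#'
#' Draws parents per the spec's kind mix, forms the linear predictor
#' eta = b0 + sum(effect_j * standardized parent_j) with the intercept
#' solved so the marginal prevalence matches the spec, samples the binary
#' target from Bernoulli(plogis(eta)), builds distractors as
#' rho * z(parent) + sqrt(1 - rho^2) * noise (assigned to parents
#' round-robin), fills the remaining columns with independent noise of
#' mixed kinds, and finally injects label-independent (MCAR) missingness —
#' a uniform cell rate plus a few noise columns pushed above the 50%
#' filter threshold.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `table` (a [cohort_table()] containing `NA` for
#'   missing cells), `target` (a `target_vector`), and `truth` (class
#'   `causal_truth`): parent names, `distractor_map`, noise variable
#'   names, the generative coefficients, and a Monte-Carlo `bayes_auc`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    p <- spec$n_variables; n <- spec$n_subjects
    npar <- spec$n_parents; ndis <- spec$n_correlated_distractors
    nn <- p - npar - ndis

    mix <- spec$kind_mix / sum(spec$kind_mix)
    counts <- round(mix * p)
    counts[1] <- p - sum(counts[-1])
    all_kinds <- sample(rep(names(mix), counts))

    vn <- sprintf("V%03d", seq_len(p))
    roles <- sample(seq_len(p))
    parent_idx <- roles[seq_len(npar)]
    distractor_idx <- if (ndis) roles[npar + seq_len(ndis)] else integer(0)
    noise_idx <- if (nn) roles[npar + ndis + seq_len(nn)] else integer(0)

    X <- matrix(NA_real_, n, p, dimnames = list(NULL, vn))
    Zpar <- matrix(0, n, npar)
    for (j in seq_len(npar)) {
      k <- all_kinds[parent_idx[j]]
      v <- draw_kind(k, n)
      X[, parent_idx[j]] <- v
      Zpar[, j] <- standardize_kind(v, k)
    }
    beta <- spec$parent_effects
    s <- drop(Zpar %*% beta)

    par_kinds <- all_kinds[parent_idx]
    draw_s <- function(m) {
      Z <- vapply(seq_len(npar), function(j)
        standardize_kind(draw_kind(par_kinds[j], m), par_kinds[j]),
        numeric(m))
      drop(Z %*% beta)
    }
    b0 <- solve_intercept(draw_s, spec$target_prevalence)
    y <- stats::rbinom(n, 1, stats::plogis(b0 + s))

    dmap <- character(0)
    if (ndis) {
      parent_of <- rep(seq_len(npar), length.out = ndis)
      rho <- spec$distractor_correlation
      for (d in seq_len(ndis)) {
        X[, distractor_idx[d]] <-
          rho * Zpar[, parent_of[d]] + sqrt(1 - rho^2) * stats::rnorm(n)
        all_kinds[distractor_idx[d]] <- "continuous"
      }
      dmap <- stats::setNames(vn[parent_idx][parent_of], vn[distractor_idx])
    }
    for (i in noise_idx) X[, i] <- draw_kind(all_kinds[i], n)

    # MCAR missingness; high-missingness columns drawn from noise only so
    # the planted structure stays identifiable after the >50% filter
    if (spec$missing_rate > 0)
      X[matrix(stats::runif(n * p) < spec$missing_rate, n, p)] <- NA
    hm <- min(spec$high_missing_columns, length(noise_idx))
    if (hm > 0) {
      for (i in sample(noise_idx, hm)) {
        drop_rows <- sample.int(n, ceiling(0.6 * n))
        X[drop_rows, i] <- NA
      }
    }

    # Monte-Carlo Bayes AUC of the true linear predictor
    bayes <- mc_bayes_auc(draw_s, b0, n_mc = 4e4)

    table <- cohort_table(X, kinds = all_kinds)
    target <- structure(list(labels = as.integer(y), cutoff = NA_real_,
                             raw_scores = NULL),
                        class = "target_vector")
    truth <- structure(
      list(parents = vn[parent_idx],
           distractor_map = dmap,
           noise_variables = vn[noise_idx],
           parent_kinds = stats::setNames(par_kinds, vn[parent_idx]),
           effects = stats::setNames(beta, vn[parent_idx]),
           intercept = b0,
           bayes_auc = bayes$auc),
      class = "causal_truth")
    list(table = table, target = target, truth = truth)
  })
}

mc_bayes_auc <- function(draw_s, b0, n_mc = 4e4) {
  s <- draw_s(n_mc)
  if (all(s == 0)) return(list(auc = 0.5, se = 0))
  y <- stats::rbinom(n_mc, 1, stats::plogis(b0 + s))
  if (length(unique(y)) < 2) return(list(auc = 0.5, se = NA_real_))
  auc <- compute_auc(s, y)
  n1 <- sum(y); n0 <- n_mc - n1
  # Hanley-McNeil standard error
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  list(auc = auc, se = se)
}

#' Monte-Carlo Bayes-optimal AUC of a planted-structure cohort
#'
#' The AUC achieved by the true linear predictor, an upper bound for any
#' classifier on data from the generator. Estimated by simulating fresh
#' subjects from the generative parameters.
#'
#' @param truth A `causal_truth` from [generate_cohort()].
#' @param n_mc Monte-Carlo sample size (default 40000).
#' @param seed Seed for the Monte-Carlo draw.
#' @return List with `auc` and its standard error `se`.
#' @export
bayes_auc_oracle <- function(truth, n_mc = 4e4, seed = 1) {
  beta <- truth$effects
  kinds <- truth$parent_kinds
  draw_s <- function(m) {
    Z <- vapply(seq_along(beta), function(j)
      standardize_kind(draw_kind(kinds[j], m), kinds[j]), numeric(m))
    drop(Z %*% beta)
  }
  with_seed(seed, mc_bayes_auc(draw_s, truth$intercept, n_mc))
}

#' @export
print.causal_truth <- function(x, ...) {
  cat(sprintf("causal_truth: %d parents, %d distractors, bayes AUC %.3f\n",
              length(x$parents), length(x$distractor_map), x$bayes_auc))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the cohort in the tab-delimited dialect [read_cohort()] reads,
#' and the ground truth as JSON.
#'
#' @param cohort List from [generate_cohort()].
#' @param path Cohort TSV path.
#' @param truth_path Optional JSON path for the ground truth.
#' @export
write_synthetic <- function(cohort, path, truth_path = NULL) {
  write_cohort(cohort$table, path)
  if (!is.null(truth_path)) {
    tr <- cohort$truth
    jsonlite::write_json(
      list(parents = tr$parents,
           distractor_map = as.list(tr$distractor_map),
           noise_variables = tr$noise_variables,
           effects = as.list(tr$effects),
           intercept = tr$intercept, bayes_auc = tr$bayes_auc),
      truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
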