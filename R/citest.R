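#' Build a conditional-independence testing context
#'
#' Precomputes the sufficient statistics used by [test_ci()] so that the
#' many tests issued by HITON-PC reuse one pass over the data: the full
#' correlation matrix for the Fisher-z test, or integer level codes (with
#' continuous variables median-discretized) for the G-squared test. The
#' target, when supplied, enters the context as pseudo-variable `".T"`.
#'
#' @param table A complete [cohort_table()] or numeric matrix (no missing
#'   values).
#' @param target Optional `target_vector` or 0/1 vector appended as `".T"`.
#' @param method `"fisher_z"` (default; partial-correlation z-test, discrete
#'   variables entered numerically) or `"g2"` (likelihood-ratio test on
#'   contingency tables; continuous variables are median-split first).
#' @param alpha Significance level used by the independence decision.
#' @param min_expected Reliability heuristic for `"g2"`: every non-empty
#'   conditioning stratum must have average expected cell count at least
#'   this value, else the test is flagged unreliable and does not reject.
#' @param min_effective_n Reliability heuristic for `"fisher_z"`: the
#'   effective sample size n - |Z| - 3 must be at least this value.
#' @return An object of class `ci_context`.
#' @export
ci_context <- function(table, target = NULL,
                       method = c("fisher_z", "g2"),
                       alpha = 0.05, min_expected = 5,
                       min_effective_n = 10) {
  method <- match.arg(method)
  M <- as_values(table)
  if (anyNA(M)) stop("CI testing requires complete data: impute first")
  if (!is.null(target)) {
    y <- as_labels(target)
    if (length(y) != nrow(M)) stop("target length does not match table")
    M <- cbind(M, ".T" = as.numeric(y))
  }
  ctx <- list(method = method, alpha = alpha, n = nrow(M),
              vars = colnames(M), min_expected = min_expected,
              min_effective_n = min_effective_n)
  if (method == "fisher_z") {
    sds <- apply(M, 2, stats::sd)
    C <- suppressWarnings(stats::cor(M))
    C[!is.finite(C)] <- 0
    diag(C) <- 1
    ctx$corr <- C
    ctx$zero_var <- sds == 0
  } else {
    codes <- lapply(seq_len(ncol(M)), function(j) {
      v <- M[, j]
      u <- sort(unique(v))
      if (length(u) > 10 || (length(u) > 2 && any(u != round(u)))) {
        med <- stats::median(v)
        as.integer(v > med)
      } else {
        match(v, u) - 1L
      }
    })
    names(codes) <- colnames(M)
    ctx$codes <- codes
    ctx$nlev <- vapply(codes, function(cd) length(unique(cd)), integer(1))
    ctx$zero_var <- ctx$nlev <= 1L
  }
  names(ctx$zero_var) <- colnames(M)
  class(ctx) <- "ci_context"
  ctx
}

# G2 likelihood-ratio test of x _||_ y | Z on integer-coded data.
g2_stat <- function(xc, yc, Zc, rx, ry, rz, min_expected) {
  if (length(Zc) == 0) {
    strata <- rep(1L, length(xc))
  } else {
    strata <- as.integer(interaction(as.data.frame(Zc), drop = TRUE))
  }
  g2 <- 0
  reliable <- TRUE
  for (s in unique(strata)) {
    idx <- strata == s
    ns <- sum(idx)
    O <- table(factor(xc[idx], levels = 0:(rx - 1)),
               factor(yc[idx], levels = 0:(ry - 1)))
    if (ns / (rx * ry) < min_expected) reliable <- FALSE
    E <- outer(rowSums(O), colSums(O)) / ns
    pos <- O > 0 & E > 0
    g2 <- g2 + 2 * sum(O[pos] * log(O[pos] / E[pos]))
  }
  dof <- (rx - 1) * (ry - 1) * prod(rz)
  list(statistic = g2, dof = dof,
       p_value = stats::pchisq(g2, df = max(dof, 1), lower.tail = FALSE),
       reliable = reliable)
}

# Fisher-z test on the partial correlation of x and y given Z.
fisher_z_stat <- function(C, x, y, Z, n, min_effective_n) {
  if (length(Z) == 0) {
    r <- C[x, y]
  } else {
    S <- C[c(x, y, Z), c(x, y, Z), drop = FALSE]
    P <- tryCatch(solve(S), error = function(e) NULL)
    if (is.null(P)) {
      # collinear conditioning set: regularize slightly
      P <- tryCatch(solve(S + diag(1e-8, nrow(S))), error = function(e) NULL)
      if (is.null(P))
        return(list(statistic = 0, dof = 0, p_value = 1, reliable = FALSE))
    }
    r <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  }
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  eff_n <- n - length(Z) - 3
  if (eff_n < 1)
    return(list(statistic = 0, dof = 0, p_value = 1, reliable = FALSE))
  z <- sqrt(eff_n) * atanh(r)
  list(statistic = z, dof = eff_n,
       p_value = 2 * stats::pnorm(-abs(z)),
       reliable = eff_n >= min_effective_n)
}

#' Conditional-independence test
#'
#' Tests x independent of y given the conditioning set Z. With method
#' `"g2"` (all variables discrete after median-split of continuous ones)
#' this is the likelihood-ratio G-squared test with
#' dof = (|x|-1)(|y|-1) * prod(|z|); with `"fisher_z"` it is the z-test on
#' the partial correlation of x and y given Z. Independence is declared
#' (see [ci_is_indep()]) when p > alpha *or* the test is unreliable by the
#' sample-size heuristic — unreliable tests never reject, the standard
#' guard in constraint-based discovery at modest n.
#'
#' @param x,y Variable names (or `".T"` for the target in a context built
#'   with one).
#' @param Z Character vector of conditioning variable names (default none).
#' @param table A complete [cohort_table()] / matrix, or a prebuilt
#'   [ci_context()].
#' @param target Optional target appended as `".T"` (ignored when `table`
#'   is already a context).
#' @param method,alpha Passed to [ci_context()] when needed.
#' @param max_k Maximum allowed conditioning-set size; exceeding it is a
#'   caller error.
#' @return A `ci_result`: list with `statistic`, `p_value`, `dof` (discrete
#'   dof or effective n), `test_name`, `conditioning_set`, `reliable`.
#' @export
test_ci <- function(x, y, Z = character(), table, target = NULL,
                    method = c("fisher_z", "g2"), alpha = 0.05,
                    max_k = Inf) {
  ctx <- if (inherits(table, "ci_context")) table
         else ci_context(table, target = target, method = method,
                         alpha = alpha)
  if (length(Z) > max_k)
    stop("conditioning set larger than max_k = ", max_k)
  if (x == y || x %in% Z || y %in% Z)
    stop("x, y and Z must be distinct")
  stopifnot(all(c(x, y, Z) %in% ctx$vars))
  if (ctx$zero_var[x] || ctx$zero_var[y]) {
    res <- list(statistic = 0, dof = 0, p_value = 1, reliable = FALSE)
  } else if (ctx$method == "fisher_z") {
    res <- fisher_z_stat(ctx$corr, x, y, Z, ctx$n, ctx$min_effective_n)
  } else {
    res <- g2_stat(ctx$codes[[x]], ctx$codes[[y]],
                   ctx$codes[Z], ctx$nlev[x], ctx$nlev[y],
                   ctx$nlev[Z], ctx$min_expected)
  }
  structure(list(statistic = unname(res$statistic),
                 p_value = unname(res$p_value),
                 dof = unname(res$dof),
                 test_name = if (ctx$method == "g2") "G2" else "fisher_z",
                 conditioning_set = Z, reliable = res$reliable,
                 alpha = ctx$alpha),
            class = "ci_result")
}

#' Independence decision for a CI test result
#'
#' @param res A `ci_result` from [test_ci()].
#' @param alpha Significance level (defaults to the one in the result).
#' @return `TRUE` when independence is declared: p > alpha or the test is
#'   unreliable.
#' @export
ci_is_indep <- function(res, alpha = res$alpha) {
  res$p_value > alpha || !res$reliable
}

#' @export
print.ci_result <- function(x, ...) {
  cat(sprintf("%s: stat=%.4g, p=%.4g, dof=%g, reliable=%s | Z={%s}\n",
              x$test_name, x$statistic, x$p_value, x$dof, x$reliable,
              paste(x$conditioning_set, collapse = ",")))
  invisible(x)
}

#' Rank variables by unconditional association with the target
#'
#' Tests every variable against the target with an empty conditioning set
#' and returns those passing the alpha filter (reliable and p <= alpha),
#' strongest first. Ties in p are broken by descending |statistic| then by
#' variable name, so the ordering is deterministic.
#'
#' @param target A `target_vector` or 0/1 vector.
#' @param table A complete [cohort_table()] / matrix, or a [ci_context()]
#'   that already contains `".T"`.
#' @param alpha Significance level of the filter.
#' @param method CI test, see [ci_context()].
#' @return A data.frame with columns `variable`, `p_value`, `statistic`,
#'   ordered by ascending p.
#' @export
association_rank <- function(target = NULL, table,
                             alpha = 0.05, method = "fisher_z") {
  ctx <- if (inherits(table, "ci_context")) table
         else ci_context(table, target = target, method = method,
                         alpha = alpha)
  stopifnot(".T" %in% ctx$vars)
  vars <- setdiff(ctx$vars, ".T")
  if (length(vars) == 0)
    return(data.frame(variable = character(), p_value = numeric(),
                      statistic = numeric(), stringsAsFactors = FALSE))
  res <- lapply(vars, function(v) test_ci(v, ".T", character(), ctx))
  keep <- vapply(res, function(r) !ci_is_indep(r, alpha), logical(1))
  df <- data.frame(variable = vars,
                   p_value = vapply(res, `[[`, numeric(1), "p_value"),
                   statistic = vapply(res, `[[`, numeric(1), "statistic"),
                   stringsAsFactors = FALSE)[keep, , drop = FALSE]
  df <- df[order(df$p_value, -abs(df$statistic), df$variable), , drop = FALSE]
  rownames(df) <- NULL
  df
}
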