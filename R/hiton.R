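#' Semi-interleaved HITON-PC without symmetry correction
#'
#' Estimates the parents-and-children (PC) set of the target: its direct
#' causes and direct effects in the underlying causal graph. For a terminal
#' target (one with no children, hence no spouses) the PC set coincides
#' with the Markov boundary — the minimal variable set carrying all
#' non-redundant predictive information about the target — which is why the
#' selected variables can be used as a compact maximally predictive feature
#' set.
#'
#' Algorithm: (1) rank all variables by unconditional association with the
#' target and keep those passing the alpha filter (the open list, strongest
#' first); (2) pop candidates one at a time into the tentative PC set
#' (TPC); as each is admitted, immediately try to eliminate it by testing
#' it against the target conditioned on every subset of the other TPC
#' members up to size `max_k` — if any subset renders it independent it is
#' discarded permanently with that witness subset recorded; (3) once the
#' open list is exhausted, a final backward pass re-tests every TPC member
#' against subsets of the others, removing any member now separable; (4)
#' the survivors are returned. No symmetry (AND-) correction is applied:
#' the reciprocal-membership check of the symmetric variant is omitted.
#'
#' Conditioning subsets are enumerated in increasing size and the earliest
#' separating subset is recorded as the witness, so witnesses are the
#' cheapest found. All orderings and tie-breaks are deterministic, so the
#' output is reproducible for fixed data and parameters.
#'
#' @param table A complete [cohort_table()] or numeric matrix.
#' @param target A `target_vector` or 0/1 vector.
#' @param alpha Significance level of every CI test (default 0.05).
#' @param max_k Maximum conditioning-set size (default 3).
#' @param method CI test: `"fisher_z"` (default) or `"g2"`, see
#'   [ci_context()].
#' @return An object of class `pc_set`: list with `selected` (survivor
#'   names in admission order), `admission_order` (every variable ever
#'   admitted to TPC), `eliminated` (data.frame of variable, phase, and the
#'   witness conditioning set that separated it), `univariate` (the
#'   association ranking), and `params`.
#' @export
run_hiton_pc <- function(table, target, alpha = 0.05, max_k = 3,
                         method = c("fisher_z", "g2")) {
  method <- match.arg(method)
  stopifnot(max_k >= 1)
  ctx <- ci_context(table, target = target, method = method, alpha = alpha)
  open <- association_rank(table = ctx, alpha = alpha)

  tpc <- character()
  admission <- character()
  elim_var <- character(); elim_phase <- character(); elim_wit <- list()

  for (cand in open$variable) {
    admission <- c(admission, cand)
    wit <- find_separator(cand, tpc, ctx, alpha, max_k)
    if (is.null(wit)) {
      tpc <- c(tpc, cand)
    } else {
      elim_var <- c(elim_var, cand)
      elim_phase <- c(elim_phase, "interleaved")
      elim_wit <- c(elim_wit, list(wit))
    }
  }

  # final backward pass over the tentative PC set
  for (m in tpc) {
    others <- setdiff(tpc, m)
    wit <- find_separator(m, others, ctx, alpha, max_k)
    if (!is.null(wit)) {
      tpc <- setdiff(tpc, m)
      elim_var <- c(elim_var, m)
      elim_phase <- c(elim_phase, "backward")
      elim_wit <- c(elim_wit, list(wit))
    }
  }

  structure(
    list(selected = tpc,
         admission_order = admission,
         eliminated = data.frame(variable = elim_var, phase = elim_phase,
                                 witness = I(elim_wit),
                                 stringsAsFactors = FALSE),
         univariate = open,
         params = list(alpha = alpha, max_k = max_k, ci_test = method)),
    class = "pc_set")
}

# Smallest subset of `pool` (size 1..max_k, enumerated in increasing size,
# within a size in combn order over pool's admission order) that renders
# `x` independent of the target; NULL if none.
find_separator <- function(x, pool, ctx, alpha, max_k) {
  pool <- setdiff(pool, x)
  if (length(pool) == 0) return(NULL)
  for (s in seq_len(min(max_k, length(pool)))) {
    subs <- utils::combn(pool, s, simplify = FALSE)
    for (Z in subs) {
      res <- test_ci(x, ".T", Z, ctx)
      if (ci_is_indep(res, alpha)) return(Z)
    }
  }
  NULL
}

#' @export
print.pc_set <- function(x, ...) {
  cat(sprintf("pc_set (%s, alpha=%g, max_k=%d): %d selected of %d admitted\n",
              x$params$ci_test, x$params$alpha, x$params$max_k,
              length(x$selected), length(x$admission_order)))
  if (length(x$selected))
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Run HITON-PC on a training fold
#'
#' Identical algorithm to [run_hiton_pc()], scoped to the training subjects
#' of a cross-validation fold so that no held-out subject influences
#' selection. Warns when the fold contains fewer than two positive
#' subjects (selection proceeds but has little power).
#'
#' @param train_table Training-fold [cohort_table()] (complete).
#' @param train_target Training-fold labels.
#' @param params List with `alpha`, `max_k`, `ci_test` (defaults 0.05, 3,
#'   `"fisher_z"`).
#' @return A `pc_set`.
#' @export
select_within_fold <- function(train_table, train_target,
                               params = list()) {
  y <- as_labels(train_target)
  if (sum(y) < 2 || sum(1 - y) < 2)
    warning("fewer than 2 subjects in a class: selection has little power")
  run_hiton_pc(train_table, y,
               alpha = params$alpha %||% 0.05,
               max_k = params$max_k %||% 3,
               method = params$ci_test %||% "fisher_z")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
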