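# Small fixtures built in code.

# complete continuous cohort with given dims
toy_cohort <- function(n = 20, p = 4, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  cohort_table(X, kinds = rep("continuous", p))
}

# write a small delimited file, returning its path
write_toy_file <- function(lines, sep = "\t") {
  path <- tempfile(fileext = ".tsv")
  writeLines(vapply(lines, paste, character(1), collapse = sep), path)
  path
}

# labels with a fixed number of positives
toy_labels <- function(n, n_pos, seed = 1) {
  set.seed(seed)
  sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
}

# brute-force AUC by explicit case-control pair enumeration
pair_auc <- function(scores, labels) {
  cases <- scores[labels == 1]; controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}
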