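# independent brute-force G2 from raw contingency counts (array algebra,
# no data expansion, separate code path from the package's test)
brute_g2 <- function(counts) {   # counts: rx x ry x (strata) array
  if (length(dim(counts)) == 2) counts <- array(counts, c(dim(counts), 1))
  g2 <- 0
  for (s in seq_len(dim(counts)[3])) {
    O <- counts[, , s]
    n <- sum(O)
    if (n == 0) next
    E <- outer(rowSums(O), colSums(O)) / n
    for (i in seq_len(nrow(O))) for (j in seq_len(ncol(O)))
      if (O[i, j] > 0 && E[i, j] > 0)
        g2 <- g2 + 2 * O[i, j] * log(O[i, j] / E[i, j])
  }
  g2
}

# expand a 2x2 (x strata) count array into subject-level data
expand_counts <- function(counts) {
  if (length(dim(counts)) == 2) counts <- array(counts, c(dim(counts), 1))
  rows <- NULL
  for (s in seq_len(dim(counts)[3]))
    for (i in 1:dim(counts)[1]) for (j in 1:dim(counts)[2]) {
      k <- counts[i, j, s]
      if (k > 0)
        rows <- rbind(rows, matrix(rep(c(i - 1, j - 1, s - 1), k),
                                   ncol = 3, byrow = TRUE))
    }
  colnames(rows) <- c("x", "y", "z")
  rows
}

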