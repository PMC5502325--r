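#' Construct a cohort table
#'
#' A cohort table is the package's central data container: a numeric
#' subjects-by-variables matrix together with a missingness mask, per-variable
#' kind declarations (binary / categorical / continuous) and subject
#' identifiers. All downstream stages (missingness filtering, imputation,
#' normalization, conditional-independence testing, cross-validation) operate
#' on this container.
#'
#' @param values Numeric matrix, subjects in rows, variables in columns.
#'   `NA` entries are taken as missing. Column names are the variable names
#'   and must be unique.
#' @param kinds Character vector of variable kinds, one of `"binary"`,
#'   `"categorical"`, `"continuous"` per column. If `NULL`, kinds are
#'   inferred with [infer_kinds()].
#' @param subject_ids Character vector of unique subject identifiers; row
#'   names of `values` are used when present, otherwise `"S1"`, `"S2"`, ...
#' @return An object of class `cohort_table` with components `values`
#'   (numeric matrix, `NA` where missing), `missing` (logical matrix),
#'   `kinds`, and `subject_ids`.
#' @export
cohort_table <- function(values, kinds = NULL, subject_ids = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  vn <- colnames(values)
  if (is.null(vn) && ncol(values) > 0) {
    vn <- paste0("V", seq_len(ncol(values)))
    colnames(values) <- vn
  }
  if (is.null(vn)) vn <- character(0)
  if (anyDuplicated(vn))
    stop("duplicate variable names: ",
         paste(unique(vn[duplicated(vn)]), collapse = ", "))
  if (is.null(subject_ids)) {
    subject_ids <- rownames(values)
    if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  if (length(subject_ids) != nrow(values))
    stop("subject_ids length does not match row count")
  rownames(values) <- subject_ids
  missing <- is.na(values)
  if (is.null(kinds)) kinds <- infer_kinds(values)
  if (length(kinds) != ncol(values))
    stop("kinds length does not match variable count")
  if (length(kinds) > 0)
    kinds <- match.arg(kinds, c("binary", "categorical", "continuous"),
                       several.ok = TRUE)
  names(kinds) <- vn
  structure(
    list(values = values, missing = missing, kinds = kinds,
         subject_ids = subject_ids),
    class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d subjects x %d variables (%d missing cells, %.1f%%)\n",
              nrow(x$values), ncol(x$values), sum(x$missing),
              100 * mean(x$missing)))
  cat("kinds:", paste(sprintf("%s=%d", names(table(x$kinds)), table(x$kinds)),
                      collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$values)

#' Variable names of a cohort table
#' @param table A `cohort_table`.
#' @return Character vector of variable names.
#' @export
variable_names <- function(table) colnames(table$values)

#' Subset a cohort table
#'
#' @param x A `cohort_table`.
#' @param i Subject (row) index.
#' @param j Variable (column) index.
#' @param ... Ignored.
#' @return A `cohort_table` restricted to the requested subjects/variables.
#' @export
`[.cohort_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  # bootstrap-style duplicated rows get disambiguated ids
  cohort_table(x$values[i, j, drop = FALSE],
               kinds = unname(x$kinds[j]),
               subject_ids = make.unique(x$subject_ids[i]))
}

#' Infer variable kinds from observed values
#'
#' A variable with at most two distinct observed values is `binary`; an
#' all-integer variable with at most `max_levels` distinct values is
#' `categorical`; anything else is `continuous`. Kinds can be overridden
#' through the sidecar configuration of [read_cohort()].
#'
#' @param values Numeric matrix (NA = missing).
#' @param max_levels Maximum number of integer levels still called
#'   categorical (default 10).
#' @return Character vector of kinds, one per column.
#' @export
infer_kinds <- function(values, max_levels = 10) {
  apply(values, 2, function(v) {
    v <- v[!is.na(v)]
    u <- unique(v)
    if (length(u) <= 2) return("binary")
    if (all(u == round(u)) && length(u) <= max_levels) return("categorical")
    "continuous"
  })
}

#' Read a delimited cohort file
#'
#' Reads a subjects-by-variables table from tab-delimited (default) or CSV
#' text with a header row of variable names. Empty cells and the configured
#' sentinel strings are flagged missing. Duplicate column names and ragged
#' rows are hard errors. An optional sidecar configuration (YAML) can name
#' the outcome column, set the outcome cutoff, and override inferred
#' variable kinds.
#'
#' @param path Path to the text file.
#' @param sep Field separator: `"\t"` (default) or `","`.
#' @param na_strings Strings treated as missing, default
#'   `c("", "NA", "NaN")`.
#' @param config Optional path to a YAML sidecar with any of the keys
#'   `outcome`, `cutoff`, `kinds` (a name -> kind map).
#' @param quiet Suppress the row/column log message.
#' @return A list with `table` (a [cohort_table()] of the predictor columns),
#'   and, when the sidecar names an outcome column, `target` (a
#'   [binarize_target()] result) plus `dropped_subjects` (ids removed for a
#'   missing outcome score). Without a sidecar, `table` holds every column.
#' @export
read_cohort <- function(path, sep = "\t", na_strings = c("", "NA", "NaN"),
                        config = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = sep, quote = "\"", blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                 path, bad, nf[bad], nf[1]))
  }
  header <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", trimws(header))
  if (anyDuplicated(header))
    stop("duplicate column names: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          na.strings = na_strings, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  vals <- suppressWarnings(
    vapply(df, function(col) as.numeric(col), numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, names(df)))
  colnames(vals) <- names(df)

  cfg <- list()
  if (!is.null(config)) cfg <- yaml::read_yaml(config)
  outcome <- cfg$outcome
  cutoff <- if (is.null(cfg$cutoff)) 38 else cfg$cutoff

  out <- list()
  if (!is.null(outcome)) {
    if (!outcome %in% colnames(vals))
      stop("outcome column not found: ", outcome)
    scores <- vals[, outcome]
    keep <- !is.na(scores)
    out$dropped_subjects <- paste0("S", which(!keep))
    if (!quiet && any(!keep))
      message(sprintf("dropped %d subjects with missing outcome", sum(!keep)))
    vals <- vals[keep, setdiff(colnames(vals), outcome), drop = FALSE]
    out$target <- binarize_target(scores[keep], cutoff = cutoff)
  }
  kinds <- infer_kinds(vals)
  if (!is.null(cfg$kinds))
    kinds[names(cfg$kinds)] <- unlist(cfg$kinds)
  out$table <- cohort_table(vals, kinds = unname(kinds))
  if (!quiet)
    message(sprintf("read %d subjects x %d variables from %s",
                    nrow(out$table$values), ncol(out$table$values), path))
  out
}

#' Write a cohort table to delimited text
#'
#' Inverse of [read_cohort()]: missing cells are written as `NA`.
#'
#' @param table A `cohort_table`.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_cohort <- function(table, path, sep = "\t") {
  utils::write.table(table$values, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Dichotomize an outcome score at a cutoff
#'
#' Labels a subject a case (1) when the raw outcome score is greater than or
#' equal to the cutoff (inclusive), mirroring the convention for symptom
#' instruments where "score of c or greater" defines the case group. The
#' default cutoff of 38 matches the UCLA PTSD Reaction Index case threshold.
#'
#' @param raw_scores Numeric vector of outcome scores, no missing values.
#' @param cutoff Real threshold; default 38.
#' @return An object of class `target_vector`: list with `labels` (0/1
#'   integer vector), `cutoff`, `raw_scores`.
#' @export
binarize_target <- function(raw_scores, cutoff = 38) {
  if (anyNA(raw_scores))
    stop("missing outcome scores: exclude those subjects upstream")
  labels <- as.integer(raw_scores >= cutoff)
  if (all(labels == 1L) || all(labels == 0L))
    warning("all labels identical (", labels[1],
            "): downstream AUC is undefined")
  structure(list(labels = labels, cutoff = cutoff, raw_scores = raw_scores),
            class = "target_vector")
}

#' @export
print.target_vector <- function(x, ...) {
  cat(sprintf("target_vector: %d subjects, %d cases (%.1f%%), cutoff %g\n",
              length(x$labels), sum(x$labels), 100 * mean(x$labels),
              x$cutoff))
  invisible(x)
}

# Coerce targets/plain vectors to a 0/1 integer label vector.
as_labels <- function(y) {
  if (inherits(y, "target_vector")) y <- y$labels
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  y
}

# Coerce cohort_table or matrix to a plain numeric matrix.
as_values <- function(x) {
  if (inherits(x, "cohort_table")) x$values else as.matrix(x)
}
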