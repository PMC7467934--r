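# Core data container, delimited-file IO, stage dichotomization and
# cross-validation splitting.

#' Construct an expression dataset
#'
#' Bundles a sample-by-feature expression matrix with its identifiers and,
#' optionally, binary stage labels (`"early"` vs `"advanced"`). This is the
#' container every other function in the package consumes.
#'
#' @param values Numeric matrix, samples in rows, features in columns. No
#'   missing values are allowed.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   row of `values`.
#' @param feature_ids Character vector of unique feature identifiers, one per
#'   column of `values`.
#' @param labels Optional factor/character vector over
#'   `c("early", "advanced")`, one per sample.
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `sample_ids`, `feature_ids` and `labels` (possibly `NULL`).
#' @export
expression_dataset <- function(values, sample_ids, feature_ids, labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(sample_ids))
    stop("number of rows of 'values' must equal length(sample_ids)")
  if (ncol(values) != length(feature_ids))
    stop("number of columns of 'values' must equal length(feature_ids)")
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature identifiers: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyNA(values))
    stop("expression values contain missing entries")
  dimnames(values) <- list(sample_ids, feature_ids)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(values))
      stop("labels must have one entry per sample")
    bad <- setdiff(unique(labels), c("early", "advanced"))
    if (length(bad))
      stop("labels must be 'early' or 'advanced'; found: ",
           paste(bad, collapse = ", "))
    labels <- factor(labels, levels = c("advanced", "early"))
  }
  structure(list(values = values, sample_ids = sample_ids,
                 feature_ids = feature_ids, labels = labels),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat(sprintf("labels: %d early, %d advanced\n",
                tab[["early"]], tab[["advanced"]]))
  } else {
    cat("labels: none attached\n")
  }
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Subset an expression dataset
#'
#' @param x An `expression_dataset`.
#' @param i Sample (row) index.
#' @param j Feature (column) index.
#' @param ... Ignored.
#' @return A new `expression_dataset` with the selected samples/features.
#' @export
`[.expression_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  v <- x$values[i, j, drop = FALSE]
  expression_dataset(v, rownames(v), colnames(v),
                     labels = if (!is.null(x$labels)) as.character(x$labels[i]))
}

#' Read a delimited expression matrix
#'
#' The expected layout is a header row of feature identifiers and a first
#' column of sample identifiers (the loader's native orientation is samples in
#' rows). Every remaining cell must parse as a real number; by default a
#' missing or unparsable cell is an error naming the offending sample and
#' feature.
#'
#' @param path Path to the delimited text file.
#' @param delimiter Field separator (default tab).
#' @param transpose If `TRUE`, the file stores features in rows and samples in
#'   columns and is transposed after reading.
#' @param missing One of `"reject"` (default; any missing cell is an error) or
#'   `"impute"` (per-feature median imputation).
#' @return An unlabeled [expression_dataset()].
#' @export
load_expression_matrix <- function(path, delimiter = "\t", transpose = FALSE,
                                   missing = c("reject", "impute")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expected at least one identifier and one value column")
  row_ids <- raw[[1]]
  col_ids <- colnames(raw)[-1]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) | vals == "" | toupper(vals) == "NA", arr.ind = TRUE)
  if (nrow(bad) && missing == "reject") {
    b <- bad[1, ]
    stop(sprintf("missing or unparsable value at sample '%s', feature '%s'",
                 if (transpose) col_ids[b[2]] else row_ids[b[1]],
                 if (transpose) row_ids[b[1]] else col_ids[b[2]]))
  }
  if (transpose) {
    num <- t(num)
    tmp <- row_ids; row_ids <- col_ids; col_ids <- tmp
  }
  if (nrow(bad) && missing == "impute") {
    for (j in unique(which(colSums(is.na(num)) > 0))) {
      med <- stats::median(num[, j], na.rm = TRUE)
      if (is.na(med)) stop("feature '", col_ids[j], "' has no observed values")
      num[is.na(num[, j]), j] <- med
    }
  }
  expression_dataset(num, row_ids, col_ids)
}

#' Write an expression dataset to a delimited file
#'
#' Values are written with 15 significant digits so that a write/read
#' round-trip preserves them to at least 12 significant digits.
#'
#' @param ds An [expression_dataset()].
#' @param path Output path.
#' @param delimiter Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(ds, path, delimiter = "\t") {
  stopifnot(inherits(ds, "expression_dataset"))
  txt <- format(ds$values, digits = 15, trim = TRUE, scientific = NA)
  out <- cbind(sample_id = ds$sample_ids, txt)
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = c("sample_id", ds$feature_ids))
  invisible(path)
}

# Parse one AJCC stage token ("I".."IV", "1".."4", optional sub-stage suffix
# such as "IIIA" or "3B", optional "Stage " prefix). Returns 1..4 or NA.
parse_stage_token <- function(token) {
  t <- toupper(trimws(token))
  t <- sub("^STAGE[ _-]*", "", t)
  m <- regmatches(t, regexec("^(IV|III|II|I|[1-4])([A-C]?)$", t))[[1]]
  if (length(m) == 0) return(NA_integer_)
  num <- switch(m[2], I = 1L, II = 2L, III = 3L, IV = 4L,
                as.integer(m[2]))
  num
}

#' Attach stage labels to a dataset
#'
#' Reads a two-column delimited file of `(sample_id, stage token)` and
#' dichotomizes AJCC stages: 1 and 2 become `"early"`, 3 and 4 become
#' `"advanced"`. Sub-stage suffixes (`"IIIA"`, `"2B"`, ...) are accepted.
#' Samples absent from the label file are dropped with a warning.
#'
#' @param ds An unlabeled [expression_dataset()].
#' @param labels Either a path to a two-column delimited file (no header
#'   required; a header line whose stage field does not parse is skipped) or a
#'   data.frame with columns `sample_id` and `stage`.
#' @param delimiter Field separator when `labels` is a path.
#' @return A labeled [expression_dataset()].
#' @export
attach_labels <- function(ds, labels, delimiter = "\t") {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.character(labels) && length(labels) == 1) {
    tab <- utils::read.table(labels, sep = delimiter, header = FALSE,
                             colClasses = "character", quote = "",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("label file must have two columns")
    if (nrow(tab) > 1 && is.na(parse_stage_token(tab[1, 2])))
      tab <- tab[-1, , drop = FALSE]  # tolerate a header line
    tab <- data.frame(sample_id = tab[[1]], stage = tab[[2]],
                      stringsAsFactors = FALSE)
  } else {
    tab <- as.data.frame(labels)
    if (!all(c("sample_id", "stage") %in% names(tab)))
      stop("labels data.frame needs columns 'sample_id' and 'stage'")
  }
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample identifiers in label table")
  num <- vapply(tab$stage, parse_stage_token, integer(1))
  if (anyNA(num))
    stop("unrecognized stage token(s): ",
         paste(unique(tab$stage[is.na(num)]), collapse = ", "))
  stage_of <- stats::setNames(ifelse(num <= 2, "early", "advanced"),
                              tab$sample_id)
  keep <- ds$sample_ids %in% names(stage_of)
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) absent from the label file were dropped: ",
            paste(utils::head(ds$sample_ids[!keep], 5), collapse = ", "),
            if (sum(!keep) > 5) ", ..." else "")
  }
  v <- ds$values[keep, , drop = FALSE]
  ids <- ds$sample_ids[keep]
  lab <- unname(stage_of[ids])
  if (!all(c("early", "advanced") %in% lab))
    stop("both classes must be present after labeling; got only ",
         paste(unique(lab), collapse = ", "))
  expression_dataset(v, ids, ds$feature_ids, labels = lab)
}

#' Stratified k-fold assignment
#'
#' Assigns each sample to one of `k` folds so that, within each class, fold
#' counts differ by at most one from the ideal proportional count. The
#' assignment is deterministic given `seed`.
#'
#' @param labels Factor or character label vector (any number of classes).
#' @param k Number of folds, at least 2. If some class has fewer than `k`
#'   members, `k` is reduced to the smallest class size with a warning.
#' @param seed Integer seed controlling the shuffle.
#' @return An object of class `cv_split`: a list with `fold` (integer vector
#'   of fold ids in `1..k`) and `k`.
#' @export
stratified_folds <- function(labels, k, seed) {
  if (!is.numeric(k) || k < 2) stop("k must be an integer >= 2")
  k <- as.integer(k)
  labels <- as.character(labels)
  n <- length(labels)
  min_class <- min(table(labels))
  if (min_class < k) {
    warning("smallest class has ", min_class, " members; reducing k from ",
            k, " to ", min_class)
    k <- as.integer(min_class)
    if (k < 2) stop("cannot build >= 2 stratified folds: a class has < 2 members")
  }
  fold <- integer(n)
  local_rng(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      # cycle fold ids from a random start so no fold is systematically larger
      start <- sample.int(k, 1)
      fold[idx] <- ((seq_along(idx) + start - 2L) %% k) + 1L
    }
  })
  structure(list(fold = fold, k = k), class = "cv_split")
}

#' Export a fold assignment for audit
#'
#' @param split A `cv_split` from [stratified_folds()].
#' @param sample_ids Sample identifiers aligned with the split.
#' @param path Output path (two-column TSV: sample_id, fold).
#' @return `path`, invisibly.
#' @export
write_cv_split <- function(split, sample_ids, path) {
  stopifnot(inherits(split, "cv_split"), length(sample_ids) == length(split$fold))
  utils::write.table(data.frame(sample_id = sample_ids, fold = split$fold),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stratified train/test partition
#'
#' @param ds A labeled [expression_dataset()].
#' @param test_fraction Fraction of each class held out for testing.
#' @param seed Integer seed.
#' @return List with `train` and `test` expression datasets and the index
#'   vectors `train_idx`, `test_idx`.
#' @export
split_train_test <- function(ds, test_fraction = 0.3, seed = 1L) {
  stopifnot(inherits(ds, "expression_dataset"), !is.null(ds$labels))
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  lab <- as.character(ds$labels)
  test_idx <- integer(0)
  local_rng(seed, {
    for (cl in sort(unique(lab))) {
      idx <- which(lab == cl)
      n_test <- max(1L, round(length(idx) * test_fraction))
      test_idx <- c(test_idx, sample(idx, n_test))
    }
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(lab), test_idx)
  list(train = ds[train_idx, ], test = ds[test_idx, ],
       train_idx = train_idx, test_idx = test_idx)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. seed = NULL uses (and advances) the current RNG.
local_rng <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
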