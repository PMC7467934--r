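# Multi-run signature consolidation by appearance score and
# main-effect-difference (MED) feature ranking.

#' Collect independent signature runs
#'
#' @param runs List of `signature_run` objects (typically 30 independent
#'   runs with distinct seeds).
#' @return An object of class `run_collection` with the runs and the
#'   per-feature appearance counts across runs.
#' @export
run_collection <- function(runs) {
  stopifnot(length(runs) >= 1,
            all(vapply(runs, inherits, TRUE, "signature_run")))
  counts <- table(unlist(lapply(runs, function(r) unique(r$selected_features))))
  structure(list(runs = runs,
                 feature_counts = stats::setNames(as.integer(counts),
                                                  names(counts))),
            class = "run_collection")
}

#' @export
print.run_collection <- function(x, ...) {
  cat(sprintf("run_collection: %d runs, %d distinct features\n",
              length(x$runs), length(x$feature_counts)))
  invisible(x)
}

#' Appearance score of one run's signature
#'
#' The mean, over the run's selected features, of how many runs in the
#' collection selected that feature. Bounded by `[1, n_runs]`; a signature
#' whose features recur in every run scores `n_runs`.
#'
#' @param run A `signature_run` belonging to `collection`.
#' @param collection A [run_collection()].
#' @return The appearance score (numeric scalar).
#' @export
appearance_score <- function(run, collection) {
  stopifnot(inherits(run, "signature_run"), inherits(collection, "run_collection"))
  feats <- unique(run$selected_features)
  if (length(feats) == 0) stop("empty signature")
  mean(collection$feature_counts[feats])
}

#' Select the most robust signature across runs
#'
#' Returns the run maximizing the appearance score; ties are broken by higher
#' fitness, then by smaller signature, then by run order.
#'
#' @param collection A [run_collection()].
#' @return The selected `signature_run`, with its appearance score attached
#'   as `$appearance_score`.
#' @export
select_robust_signature <- function(collection) {
  stopifnot(inherits(collection, "run_collection"))
  scores <- vapply(collection$runs, appearance_score, numeric(1),
                   collection = collection)
  fits <- vapply(collection$runs, function(r) r$fitness, numeric(1))
  sizes <- vapply(collection$runs, function(r) length(r$selected_features),
                  numeric(1))
  ord <- order(-scores, -fits, sizes)
  best <- collection$runs[[ord[1]]]
  best$appearance_score <- scores[ord[1]]
  best
}

# OA-design main-effect scores for K two-level include/exclude factors.
# fitness_subset(idx) must return the fitness of the subset given by the
# included factor indices; a row including no factor scores 0.
med_engine <- function(K, fitness_subset) {
  stopifnot(K >= 1)
  oa <- orthogonal_array(K)
  row_fit <- vapply(seq_len(nrow(oa)), function(j) {
    inc <- which(oa[j, ] == 1L)
    if (length(inc) == 0) 0 else fitness_subset(inc)
  }, numeric(1))
  med <- vapply(seq_len(K), function(i) {
    mean(row_fit[oa[, i] == 1L]) - mean(row_fit[oa[, i] == 2L])
  }, numeric(1))
  list(med = med * 100, oa = oa, row_fitness = row_fit)
}

#' Rank signature features by main-effect difference
#'
#' Builds a strength-2 two-level orthogonal array whose factors are the
#' signature's features (levels: include / exclude), evaluates each row's
#' included subset by pooled CV accuracy at the signature's optimized
#' hyperparameters on a fixed fold split, and scores each feature by the
#' difference between the mean fitness of rows including it and rows
#' excluding it, in accuracy percentage points. Larger MED = larger
#' contribution to predictive performance. Rows with an empty subset score 0.
#'
#' @param ds A labeled [expression_dataset()] containing all signature
#'   features.
#' @param signature A `signature_run` (its `params` are reused for
#'   comparability across features).
#' @param split A `cv_split` over the samples of `ds` (fixed across rows).
#' @param class_weights Optional named class weights.
#' @return An object of class `ranked_signature`: a data.frame with columns
#'   `rank`, `feature_id`, `med_score` (non-increasing), plus the OA design
#'   as attribute `"oa"`.
#' @export
med_rank <- function(ds, signature, split, class_weights = NULL) {
  stopifnot(inherits(ds, "expression_dataset"),
            inherits(signature, "signature_run"), inherits(split, "cv_split"))
  feats <- signature$selected_features
  missing_feats <- setdiff(feats, ds$feature_ids)
  if (length(missing_feats))
    stop("signature features absent from dataset: ",
         paste(missing_feats, collapse = ", "))
  K <- length(feats)
  if (K < 2) stop("MED ranking needs a signature of at least 2 features")
  cols <- match(feats, ds$feature_ids)
  x <- ds$values
  y <- ds$labels
  eng <- med_engine(K, function(inc) {
    pooled_cv_accuracy(x, cols[inc], y, split$fold,
                       signature$params$C, signature$params$gamma,
                       class_weights)
  })
  ord <- order(-eng$med)  # stable: first-listed feature wins ties
  out <- data.frame(rank = seq_len(K), feature_id = feats[ord],
                    med_score = eng$med[ord], stringsAsFactors = FALSE)
  attr(out, "oa") <- eng$oa
  attr(out, "row_fitness") <- eng$row_fitness
  class(out) <- c("ranked_signature", "data.frame")
  out
}

#' Export a ranked signature as TSV
#'
#' Columns `rank`, `feature_id`, `med_score`.
#'
#' @param ranked A `ranked_signature` from [med_rank()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked_signature <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_signature"))
  utils::write.table(as.data.frame(ranked)[, c("rank", "feature_id", "med_score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
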