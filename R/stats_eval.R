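# Classification metrics, ROC/AUC, Hanley-McNeil AUC standard errors and
# two-AUC comparison, and the correlation analyses (Pearson co-expression,
# Spearman clinical correlation).

#' Confusion counts
#'
#' Standard 2x2 table counts with a configurable positive class.
#'
#' @param pred Predicted labels.
#' @param truth True labels (same length).
#' @param positive The label counted as positive (default `"early"`).
#' @return An object of class `confusion_counts`: list with `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion_counts <- function(pred, truth, positive = "early") {
  if (length(pred) != length(truth)) stop("pred and truth must have equal length")
  pred <- as.character(pred)
  truth <- as.character(truth)
  p <- pred == positive
  t <- truth == positive
  structure(list(TP = sum(p & t), TN = sum(!p & !t),
                 FP = sum(p & !t), FN = sum(!p & t)),
            class = "confusion_counts")
}

#' Sensitivity, specificity, MCC and accuracy
#'
#' `SN = TP/(TP+FN)`, `SP = TN/(TN+FP)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`. A zero denominator yields `NA` for SN/SP
#' and 0 for MCC (the degenerate-classifier convention).
#'
#' @param cc A [confusion_counts()] object, or `TP`,`TN`,`FP`,`FN` given
#'   directly via `...`.
#' @param ... Ignored.
#' @return List with `sn`, `sp`, `mcc`, `acc`.
#' @export
classification_metrics <- function(cc, ...) {
  stopifnot(inherits(cc, "confusion_counts"))
  TP <- cc$TP; TN <- cc$TN; FP <- cc$FP; FN <- cc$FN
  total <- TP + TN + FP + FN
  if (total < 1) stop("empty confusion table")
  sn <- if (TP + FN == 0) NA_real_ else TP / (TP + FN)
  sp <- if (TN + FP == 0) NA_real_ else TN / (TN + FP)
  denom <- sqrt(as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- if (denom == 0) 0 else (as.numeric(TP) * TN - as.numeric(FP) * FN) / denom
  list(sn = sn, sp = sp, mcc = mcc, acc = (TP + TN) / total)
}

#' Area under the ROC curve
#'
#' The all-pairs concordance probability (ties count one half), computed from
#' midranks; identical to the trapezoidal area under the empirical ROC curve
#' and to the Mann-Whitney statistic scaled by `n_pos * n_neg`.
#'
#' @param scores Numeric decision scores (larger = more positive).
#' @param labels Labels; both classes must be present.
#' @param positive The positive label (default `"early"`).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels, positive = "early") {
  labels <- as.character(labels)
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC points
#'
#' @param scores,labels,positive As in [auc_score()].
#' @return data.frame with columns `fpr`, `tpr`, one row per threshold
#'   (including the (0,0) and (1,1) endpoints), suitable for TSV export.
#' @export
roc_points <- function(scores, labels, positive = "early") {
  labels <- as.character(labels)
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  keep <- c(diff(scores[ord]) != 0, TRUE)  # one point per distinct threshold
  data.frame(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1))
}

#' Hanley-McNeil standard error of an empirical AUC
#'
#' `SE = sqrt((A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)) /
#' (n_pos n_neg))` with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`.
#'
#' @param a AUC in `[0, 1]`.
#' @param n_pos,n_neg Class sizes (at least 1).
#' @return The standard error.
#' @export
hanley_mcneil_se <- function(a, n_pos, n_neg) {
  if (!is.numeric(a) || a < 0 || a > 1) stop("AUC must be in [0, 1]")
  if (n_pos < 1 || n_neg < 1) stop("class sizes must be >= 1")
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) + (n_neg - 1) * (q2 - a^2)) /
         (n_pos * n_neg))
}

#' Compare two AUCs (Hanley-McNeil z-test)
#'
#' `z = (auc1 - auc2) / sqrt(se1^2 + se2^2 - 2 r se1 se2)` with a two-sided
#' normal p-value. `r` is the correlation between the two AUC estimates
#' (0 for independent samples; supply the paired-design correlation when the
#' AUCs come from the same cases).
#'
#' @param auc1,auc2 The two AUCs.
#' @param n_pos,n_neg Class sizes underlying both AUCs.
#' @param r Correlation between the AUC estimates, in `[-1, 1]` (default 0).
#' @return An object of class `auc_comparison`: list with `auc1`, `auc2`,
#'   `se1`, `se2`, `auc_diff`, `z`, `p`. A zero-variance comparison yields
#'   `z = NA`, `p = NA`.
#' @export
compare_aucs <- function(auc1, auc2, n_pos, n_neg, r = 0) {
  if (abs(r) > 1) stop("|r| must be <= 1")
  se1 <- hanley_mcneil_se(auc1, n_pos, n_neg)
  se2 <- hanley_mcneil_se(auc2, n_pos, n_neg)
  v <- se1^2 + se2^2 - 2 * r * se1 * se2
  if (v <= 0) {
    z <- NA_real_
    p <- NA_real_
  } else {
    z <- (auc1 - auc2) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc1 = auc1, auc2 = auc2, se1 = se1, se2 = se2,
                 auc_diff = auc1 - auc2, z = z, p = p),
            class = "auc_comparison")
}

#' Pearson correlation matrix of selected features
#'
#' @param ds An [expression_dataset()] with at least 2 samples.
#' @param features Feature ids or column indices (default: all features).
#' @return Symmetric correlation matrix with unit diagonal. Constant features
#'   get `NA` rows/columns (with a warning).
#' @export
pearson_matrix <- function(ds, features = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  x <- ds$values
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 samples")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    warning("constant feature(s), correlation undefined: ",
            paste(colnames(x)[sds == 0], collapse = ", "))
  r <- suppressWarnings(stats::cor(x))
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  r
}

#' Features co-expressed with a signature
#'
#' For each signature feature, finds the non-signature features whose Pearson
#' correlation with it meets `threshold`, sorted by decreasing correlation.
#'
#' @param ds An [expression_dataset()].
#' @param signature_features Character vector of signature feature ids (must
#'   be a subset of the dataset's features).
#' @param threshold Minimum correlation, default 0.5.
#' @return Named list (one element per signature feature) of data.frames with
#'   columns `feature_id`, `r`.
#' @export
coexpressed_features <- function(ds, signature_features, threshold = 0.5) {
  stopifnot(inherits(ds, "expression_dataset"))
  missing_feats <- setdiff(signature_features, ds$feature_ids)
  if (length(missing_feats))
    stop("signature features absent from dataset: ",
         paste(missing_feats, collapse = ", "))
  others <- setdiff(ds$feature_ids, signature_features)
  sig_x <- ds$values[, signature_features, drop = FALSE]
  oth_x <- ds$values[, others, drop = FALSE]
  rmat <- suppressWarnings(stats::cor(sig_x, oth_x))
  out <- lapply(signature_features, function(f) {
    rv <- rmat[f, ]
    # small tolerance so exact duplicates (r = 1 up to rounding) survive a
    # threshold of exactly 1
    hit <- which(!is.na(rv) & rv >= threshold - 1e-12)
    hit <- hit[order(-rv[hit])]
    data.frame(feature_id = others[hit], r = unname(rv[hit]),
               stringsAsFactors = FALSE)
  })
  stats::setNames(out, signature_features)
}

#' Spearman correlation of features with a clinical covariate
#'
#' Rank-based correlation (midranks for ties) with a two-sided p-value from
#' the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param ds An [expression_dataset()].
#' @param features Feature ids to test (default all).
#' @param clinical Ordinal or binary numeric vector aligned with the samples;
#'   must not be constant and needs at least 3 samples.
#' @param adjust P-value adjustment: `"none"` (default) or `"BH"`
#'   (Benjamini-Hochberg).
#' @return data.frame with columns `feature_id`, `rho`, `p`.
#' @export
spearman_clinical <- function(ds, features = NULL, clinical,
                              adjust = c("none", "BH")) {
  stopifnot(inherits(ds, "expression_dataset"))
  adjust <- match.arg(adjust)
  x <- ds$values
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  clinical <- as.numeric(clinical)
  n <- nrow(x)
  if (length(clinical) != n) stop("clinical vector must align with samples")
  if (n < 3) stop("need at least 3 samples")
  if (length(unique(clinical)) < 2) stop("clinical vector is constant")
  rho <- suppressWarnings(
    as.numeric(stats::cor(x, clinical, method = "spearman")))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  data.frame(feature_id = colnames(x), rho = rho, p = p,
             stringsAsFactors = FALSE)
}

#' Metrics report for one evaluation context
#'
#' Computes ACC, SN, SP, MCC and AUC from predictions and scores, as written
#' by the evaluation pipeline.
#'
#' @param pred Predicted labels.
#' @param truth True labels.
#' @param scores Decision scores (positive = positive class).
#' @param positive Positive class label.
#' @return List with `acc`, `sn`, `sp`, `mcc`, `auc` and the
#'   `confusion_counts`.
#' @export
metrics_report <- function(pred, truth, scores, positive = "early") {
  cc <- confusion_counts(pred, truth, positive)
  m <- classification_metrics(cc)
  list(acc = m$acc, sn = m$sn, sp = m$sp, mcc = m$mcc,
       auc = auc_score(scores, truth, positive), confusion = cc)
}
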