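# RBF-kernel SVM training and the pooled cross-validated accuracy that the
# genetic algorithm maximizes. The quadratic program is delegated to libsvm
# via e1071; this module owns the kernel contract, per-fold standardization,
# the CV protocol and the fitness definition.

#' SVM hyperparameters
#'
#' @param C Soft-margin cost, strictly positive.
#' @param gamma RBF kernel width, strictly positive.
#' @return An object of class `svm_params`.
#' @export
svm_params <- function(C, gamma) {
  if (!is.numeric(C) || C <= 0) stop("C must be a positive real")
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be a positive real")
  structure(list(C = as.numeric(C), gamma = as.numeric(gamma)),
            class = "svm_params")
}

#' Radial basis function kernel
#'
#' `K(x_i, x_j) = exp(-gamma * ||x_i - x_j||^2)`, the kernel used throughout
#' the classifier. Always in `(0, 1]`.
#'
#' @param x_i,x_j Numeric vectors of equal length.
#' @param gamma Positive kernel width.
#' @return The kernel value.
#' @export
rbf_kernel <- function(x_i, x_j, gamma) {
  if (length(x_i) != length(x_j)) stop("vectors must have equal length")
  if (gamma <= 0) stop("gamma must be positive")
  exp(-gamma * sum((x_i - x_j)^2))
}

# Column means/sds fitted on a training matrix; zero-variance columns get
# sd = 1 so standardization is a no-op for them.
fit_scaler <- function(x) {
  mu <- colMeans(x)
  n <- nrow(x)
  v <- (colSums(x * x) - n * mu^2) / max(1, n - 1)
  s <- sqrt(pmax(v, 0))
  s[s < 1e-12] <- 1
  list(center = mu, scale = s)
}

apply_scaler <- function(x, sc) {
  n <- nrow(x)
  p <- length(sc$center)
  (x - matrix(sc$center, n, p, byrow = TRUE)) /
    matrix(sc$scale, n, p, byrow = TRUE)
}

#' Train an RBF-SVM stage classifier
#'
#' Standardizes each feature (zero mean, unit variance, fitted on the training
#' data only) and trains a soft-margin RBF-kernel SVM. The returned object
#' predicts classes and real-valued decision scores whose sign convention is
#' positive = `positive_class`, so scores are directly usable for ROC curves.
#'
#' @param ds A labeled [expression_dataset()] (already restricted to the
#'   features of interest, or use `features` to restrict).
#' @param params An [svm_params()] object.
#' @param features Optional character vector or index of feature columns to
#'   train on; default all.
#' @param positive_class Class mapped to positive decision scores
#'   (default `"early"`).
#' @param class_weights Optional named weights passed to the SVM (e.g.
#'   inverse class frequencies); default unweighted.
#' @return An object of class `stage_svm`.
#' @export
train_classifier <- function(ds, params, features = NULL,
                             positive_class = "early", class_weights = NULL) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(params, "svm_params"))
  if (is.null(ds$labels)) stop("dataset must be labeled")
  x <- ds$values
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  if (ncol(x) < 1) stop("at least one feature must be selected")
  y <- factor(as.character(ds$labels))
  if (nlevels(y) < 2) stop("training data must contain both classes")
  sc <- fit_scaler(x)
  xs <- apply_scaler(x, sc)
  fit <- e1071::svm(xs, y, kernel = "radial", cost = params$C,
                    gamma = params$gamma, scale = FALSE, fitted = FALSE,
                    class.weights = class_weights)
  # libsvm orients decision values toward its first internal label; detect it
  dv <- attr(stats::predict(fit, xs[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  first_label <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
  structure(list(fit = fit, scaler = sc, features = colnames(x),
                 params = params, positive_class = positive_class,
                 flip = if (identical(first_label, positive_class)) 1 else -1),
            class = "stage_svm")
}

#' Predict with a stage classifier
#'
#' @param object A `stage_svm` from [train_classifier()].
#' @param newdata An `expression_dataset` or numeric matrix containing (at
#'   least) the training features.
#' @param ... Ignored.
#' @return A list with `class` (factor of predicted labels) and `score`
#'   (numeric decision values, positive = the positive class).
#' @export
predict.stage_svm <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "expression_dataset")) newdata$values else newdata
  x <- x[, object$features, drop = FALSE]
  xs <- apply_scaler(x, object$scaler)
  p <- stats::predict(object$fit, xs, decision.values = TRUE)
  score <- object$flip * as.numeric(attr(p, "decision.values"))
  list(class = p, score = score)
}

# ---- lean libsvm fast path -------------------------------------------------
# The GA evaluates tens of thousands of candidate feature subsets, so the
# inner CV loop calls the compiled libsvm trainer in the installed e1071
# directly, skipping the R-level bookkeeping of svm()/predict.svm() (input
# coercion, NA handling, fitted values) that dominates wall time at these
# problem sizes. The argument layout mirrors e1071's own .C call; a unit test
# asserts this path reproduces e1071::svm predictions exactly.

svmtrain_symbol <- local({
  sym <- NULL
  function() {
    if (is.null(sym)) {
      loadNamespace("e1071")  # ensure the shared library is loaded
      sym <<- get("R_svmtrain", envir = asNamespace("e1071"))
    }
    sym
  }
})

# Train a binary C-classification RBF SVM. y_int: integer class codes (1/2).
# Returns support vectors, dual coefficients, rho and the libsvm label order.
fast_svm_train <- function(x, y_int, C, gamma, weightlabels = NULL,
                           weights = NULL) {
  nr <- nrow(x)
  err <- paste(rep(" ", 255), collapse = "")
  cret <- .C(svmtrain_symbol(),
             as.double(t(x)), as.integer(nr), as.integer(ncol(x)),
             as.double(y_int), 0L, 0L,
             0L,                       # type: C-classification
             2L,                       # kernel: radial
             3L, as.double(gamma), 0,  # degree, gamma, coef0
             as.double(C), 0.5,        # cost, nu
             as.integer(weightlabels), as.double(weights),
             as.integer(length(weights)),
             40, 0.001, 0.1,           # cachesize, tolerance, epsilon
             1L, 0L, 0L, 0L,           # shrinking, cross, sparse, probability
             nclasses = integer(1), nr = integer(1), index = integer(nr),
             labels = integer(2), nSV = integer(2), rho = double(1),
             coefs = double(nr), sigma = double(1), probA = double(1),
             probB = double(1), cresults = double(0), ctotal1 = double(1),
             ctotal2 = double(1), error = err)
  if (cret$error != err) stop(trimws(cret$error))
  nsv <- cret$nr
  list(SV = x[cret$index[seq_len(nsv)], , drop = FALSE],
       coefs = cret$coefs[seq_len(nsv)], rho = cret$rho,
       labels = cret$labels, gamma = gamma)
}

# Integer class predictions for the fast-path model: decision values from the
# RBF kernel against the support vectors; positive decision = labels[1].
fast_svm_decision <- function(model, x) {
  d2 <- outer(rowSums(x * x), rowSums(model$SV * model$SV), "+") -
    2 * tcrossprod(x, model$SV)
  as.numeric(exp(-model$gamma * d2) %*% model$coefs) - model$rho
}

fast_svm_predict <- function(model, x) {
  ifelse(fast_svm_decision(model, x) > 0, model$labels[1], model$labels[2])
}

# Fast inner loop shared by cv_fitness, the GA and MED ranking: pooled k-fold
# accuracy for a feature submatrix. x is the full value matrix, sel an integer
# index of selected columns, y a two-level factor, fold the per-sample fold id.
# A fold whose training complement is single-class makes the whole
# configuration score 0 (degenerate, not an error).
pooled_cv_accuracy <- function(x, sel, y, fold, C, gamma,
                               class_weights = NULL) {
  xm <- x[, sel, drop = FALSE]
  y_int <- as.integer(y)
  weightlabels <- NULL
  weights <- NULL
  if (!is.null(class_weights)) {
    weightlabels <- match(names(class_weights), levels(y))
    if (anyNA(weightlabels)) stop("class_weights names must match the labels")
    weights <- as.numeric(class_weights)
  }
  n <- nrow(xm)
  correct <- 0L
  for (f in unique(fold)) {
    te <- fold == f
    ytr <- y_int[!te]
    if (min(ytr) == max(ytr)) return(0)
    xtr <- xm[!te, , drop = FALSE]
    sc <- fit_scaler(xtr)
    fit <- fast_svm_train(apply_scaler(xtr, sc), ytr, C, gamma,
                          weightlabels, weights)
    pred <- fast_svm_predict(fit, apply_scaler(xm[te, , drop = FALSE], sc))
    correct <- correct + sum(pred == y_int[te])
  }
  correct / n
}

#' Cross-validated accuracy fitness
#'
#' The objective the genetic algorithm maximizes: pooled k-fold accuracy
#' `(TP + TN) / (TP + TN + FP + FN)` where all fold predictions are pooled
#' before counting. Feature standardization is refit on each training fold so
#' no test information leaks. A fold whose training complement contains a
#' single class yields fitness 0 for the configuration (logged as a message).
#'
#' @param ds A labeled [expression_dataset()].
#' @param mask Logical vector over features (or integer index) selecting the
#'   evaluated subset; must select at least one feature.
#' @param params An [svm_params()].
#' @param split A `cv_split` from [stratified_folds()] covering all samples.
#' @param class_weights Optional named class weights.
#' @return An object of class `fitness_result`: list with `cv_accuracy`,
#'   `n_selected` and `params`.
#' @export
cv_fitness <- function(ds, mask, params, split, class_weights = NULL) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(params, "svm_params"),
            inherits(split, "cv_split"))
  if (is.null(ds$labels)) stop("dataset must be labeled")
  sel <- if (is.logical(mask)) {
    if (length(mask) != ncol(ds$values))
      stop("mask length must equal the number of features")
    which(mask)
  } else as.integer(mask)
  if (length(sel) < 1) stop("mask must select at least one feature")
  if (length(split$fold) != nrow(ds$values))
    stop("split must cover all samples")
  acc <- pooled_cv_accuracy(ds$values, sel, ds$labels, split$fold,
                            params$C, params$gamma, class_weights)
  if (acc == 0)
    message("configuration scored 0 (a training fold was single-class or no sample was classified correctly)")
  structure(list(cv_accuracy = acc, n_selected = length(sel), params = params),
            class = "fitness_result")
}
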