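# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (double loops, direct moment formulas) and independent of
# the package's implementation paths.

# Two well-separated Gaussian clusters; first `n_inf` features informative.
make_separable_dataset <- function(n_per_class = 20, m = 5, n_inf = m,
                                   effect = 5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * m), n, m)
  lab <- rep(c("early", "advanced"), each = n_per_class)
  x[lab == "advanced", seq_len(n_inf)] <- x[lab == "advanced", seq_len(n_inf)] + effect
  expression_dataset(x, sprintf("s%02d", 1:n), sprintf("f%02d", 1:m), labels = lab)
}

# A signature_run shell for ranking/consolidation tests.
fake_run <- function(features, fitness = 0.5, C = 1, gamma = 0.1, seed = 0L) {
  structure(list(selected_features = features, params = svm_params(C, gamma),
                 fitness = fitness, per_r_best = NULL, seed = seed,
                 mask = NULL),
            class = "signature_run")
}

# O(n^2) all-pairs concordance AUC (ties count 1/2).
auc_bruteforce <- function(scores, labels, positive = "early") {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# Direct moment-formula Pearson correlation.
pearson_bruteforce <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  sum((a - ma) * (b - mb)) / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# Midranks computed naively: rank = (# smaller) + (1 + # equal) / 2.
midrank_bruteforce <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (1 + sum(x == x[i])) / 2
  }, numeric(1))
}

# Confusion-table metrics recomputed from raw label vectors (not from the
# package's confusion counts).
metrics_bruteforce <- function(pred, truth, positive = "early") {
  tp <- sum(pred == positive & truth == positive)
  tn <- sum(pred != positive & truth != positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  list(acc = (tp + tn) / length(pred),
       sn = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       sp = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
       mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

# Exhaustive optimum over all 2^F combinations of taking each differing gene
# from parent 1 or parent 2 (additive-fitness crossover oracle).
exhaustive_crossover_best <- function(g1, g2, diff, weights) {
  F <- length(diff)
  best <- -Inf
  best_genes <- NULL
  for (code in 0:(2^F - 1)) {
    g <- g1
    take2 <- diff[bitwAnd(code, bitwShiftL(1L, seq_len(F) - 1L)) > 0L]
    g[take2] <- g2[take2]
    f <- sum(weights[g])
    if (f > best) {
      best <- f
      best_genes <- g
    }
  }
  list(fitness = best, genes = best_genes)
}
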