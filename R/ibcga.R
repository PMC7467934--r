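# Inheritable bi-objective combinatorial genetic algorithm (IBCGA).
#
# A chromosome is a binary feature mask constrained to exactly r set bits
# during stage r, plus two 4-bit codes indexing the SVM hyperparameter grids.
# Each stage evolves the population for g_max generations (tournament
# selection, orthogonal-array crossover, swap mutation, elitism); the
# inheritance step then sets one extra mask bit per individual and evolution
# continues at r + 1. The returned solution maximizes fitness over all stages
# with ties broken toward fewer features (the bi-objective preference).

# Hyperparameter grids: standard libsvm-style log2 grids, 16 values each so a
# 4-bit code addresses them. C = 2^-5 .. 2^10, gamma = 2^-15 .. 2^0.
C_GRID <- 2^seq(-5L, 10L)
GAMMA_GRID <- 2^seq(-15L, 0L)

#' Decode hyperparameter grid codes
#'
#' @param c_code,g_code Integers in `0..15` indexing the cost and gamma grids.
#' @return An [svm_params()] with `C = 2^(c_code - 5)` and
#'   `gamma = 2^(g_code - 15)`.
#' @export
decode_params <- function(c_code, g_code) {
  stopifnot(c_code >= 0, c_code <= 15, g_code >= 0, g_code <= 15)
  svm_params(C_GRID[c_code + 1L], GAMMA_GRID[g_code + 1L])
}

new_chromosome <- function(mask, c_code, g_code) {
  list(mask = mask, c_code = as.integer(c_code), g_code = as.integer(g_code))
}

popcount <- function(ch) sum(ch$mask)

int_to_bits <- function(code, width = 4L) {
  as.logical(bitwAnd(as.integer(code), bitwShiftL(1L, seq_len(width) - 1L)) > 0L)
}

bits_to_int <- function(bits) {
  as.integer(sum(bitwShiftL(1L, which(bits) - 1L)))
}

# Full gene vector: mask bits then 4 cost bits then 4 gamma bits.
chromosome_genes <- function(ch) {
  c(ch$mask, int_to_bits(ch$c_code), int_to_bits(ch$g_code))
}

genes_to_chromosome <- function(genes, m) {
  new_chromosome(genes[seq_len(m)],
                 bits_to_int(genes[m + 1:4]),
                 bits_to_int(genes[m + 5:8]))
}

chromosome_key <- function(ch) {
  paste(c(which(ch$mask), 900L + ch$c_code, 1000L + ch$g_code), collapse = ",")
}

#' GA configuration
#'
#' Defaults follow the published IBCGA settings (`r_start = 10`,
#' `r_end = 50`, `n_pop = 50`, `g_max = 60` generations per stage); crossover
#' and mutation probabilities and the orthogonal-array factor cap are this
#' implementation's defaults.
#'
#' @param r_start,r_end First and last feature-subset sizes swept.
#' @param n_pop Population size (even).
#' @param g_max Generations evolved at each subset size.
#' @param p_c Probability a selected pair undergoes orthogonal-array crossover.
#' @param p_m Mutation probability (per-chromosome swap for the mask;
#'   per-bit flip for the hyperparameter codes).
#' @param tournament_size Individuals drawn per tournament (default 2).
#' @param oa_max_factors Maximum factors per crossover; more differing
#'   positions are round-robin grouped (bounds fitness evaluations per
#'   crossover at `2^ceiling(log2(oa_max_factors + 1))`).
#' @param seed Integer seed making the run deterministic.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(r_start = 10L, r_end = 50L, n_pop = 50L, g_max = 60L,
                      p_c = 0.8, p_m = 0.05, tournament_size = 2L,
                      oa_max_factors = 15L, seed = 1L) {
  if (r_start < 1 || r_end < r_start) stop("need 1 <= r_start <= r_end")
  if (n_pop < 2 || n_pop %% 2 != 0) stop("n_pop must be even and >= 2")
  if (g_max < 0) stop("g_max must be >= 0")
  if (p_c < 0 || p_c > 1 || p_m < 0 || p_m > 1) stop("p_c, p_m must be in [0, 1]")
  if (oa_max_factors < 1) stop("oa_max_factors must be >= 1")
  structure(list(r_start = as.integer(r_start), r_end = as.integer(r_end),
                 n_pop = as.integer(n_pop), g_max = as.integer(g_max),
                 p_c = p_c, p_m = p_m,
                 tournament_size = as.integer(tournament_size),
                 oa_max_factors = as.integer(oa_max_factors),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Initial population
#'
#' Each individual receives exactly `r_start` uniformly chosen mask bits and
#' uniform hyperparameter codes. Uses the current RNG state.
#'
#' @param cfg A [ga_config()].
#' @param m Number of features (must be at least `r_start`).
#' @return List of `n_pop` chromosomes.
#' @export
init_population <- function(cfg, m) {
  if (m < cfg$r_start) stop("m must be >= r_start")
  lapply(seq_len(cfg$n_pop), function(i) {
    mask <- logical(m)
    mask[sample.int(m, cfg$r_start)] <- TRUE
    new_chromosome(mask, sample.int(16L, 1L) - 1L, sample.int(16L, 1L) - 1L)
  })
}

#' Tournament selection
#'
#' Draws `k` distinct individuals uniformly and returns the index of the
#' fittest; exact ties are broken uniformly at random.
#'
#' @param fitnesses Numeric fitness vector for the population.
#' @param k Tournament size (default 2).
#' @return The selected index.
#' @export
tournament_select <- function(fitnesses, k = 2L) {
  n <- length(fitnesses)
  if (n == 0) stop("empty population")
  if (n == 1) return(1L)
  cand <- sample.int(n, min(k, n))
  f <- fitnesses[cand]
  winners <- cand[f == max(f)]
  if (length(winners) == 1) winners else winners[sample.int(length(winners), 1L)]
}

#' Two-level orthogonal array
#'
#' Builds `OA(N, n_factors, 2, 2)` from the Sylvester-Hadamard construction
#' with `N = 2^ceiling(log2(n_factors + 1))` rows: every column is balanced
#' and every pair of columns contains all four level combinations equally
#' often (strength 2).
#'
#' @param n_factors Number of two-level factors.
#' @return An `N x n_factors` integer matrix of levels 1/2.
#' @export
orthogonal_array <- function(n_factors) {
  stopifnot(n_factors >= 1)
  N <- 2^ceiling(log2(n_factors + 1))
  H <- matrix(1, 1, 1)
  while (ncol(H) < N) H <- rbind(cbind(H, H), cbind(H, -H))
  oa <- ifelse(H[, 2:(n_factors + 1), drop = FALSE] > 0, 1L, 2L)
  dimnames(oa) <- NULL
  oa
}

# Repair a mask to exactly r set bits, staying within parental material:
# surplus bits are unset among the differing positions (bits set in only one
# parent); deficit bits are set among the parents' union.
repair_mask <- function(mask, r, diff_pos, union_pos) {
  pc <- sum(mask)
  if (pc > r) {
    cand <- diff_pos[mask[diff_pos]]
    drop <- if (length(cand) == 1) cand else sample(cand, pc - r)
    mask[drop] <- FALSE
  } else if (pc < r) {
    cand <- union_pos[!mask[union_pos]]
    add <- if (length(cand) == 1) cand else sample(cand, r - pc)
    mask[add] <- TRUE
  }
  mask
}

#' Orthogonal-array crossover
#'
#' The gene positions where the parents differ are grouped into at most
#' `max_factors` two-level factors (round-robin when there are more differing
#' positions than factors); positions shared by both parents pass through
#' unchanged. Each row of a strength-2 orthogonal array defines a candidate
#' taking every factor from parent 1 (level 1) or parent 2 (level 2). All
#' candidates are evaluated with `fitness_fn`; the per-factor main effects
#' (mean candidate fitness at each level) then assemble `child1` from the
#' better level of every factor, while `child2` is the best evaluated
#' candidate row.
#'
#' When `r` is given, every candidate's mask is repaired to exactly `r` set
#' bits before evaluation; `r = NULL` runs the operator unconstrained.
#'
#' @param p1,p2 Parent chromosomes.
#' @param fitness_fn Function mapping a chromosome to a numeric fitness; a
#'   failing evaluation scores 0.
#' @param r Popcount constraint for masks, or `NULL` for unconstrained.
#' @param max_factors Factor cap (see [ga_config()]).
#' @return List with `children` (list of two chromosomes) and `fitness`
#'   (their cached fitness values).
#' @export
oa_crossover <- function(p1, p2, fitness_fn, r = NULL, max_factors = 15L) {
  m <- length(p1$mask)
  g1 <- chromosome_genes(p1)
  g2 <- chromosome_genes(p2)
  diff <- which(g1 != g2)
  d <- length(diff)
  if (d == 0) {
    f <- safe_fitness(fitness_fn, p1)
    return(list(children = list(p1, p2), fitness = c(f, f)))
  }
  n_fac <- min(d, max_factors)
  groups <- split(diff, rep(seq_len(n_fac), length.out = d))
  oa <- orthogonal_array(n_fac)
  diff_mask_pos <- diff[diff <= m]
  union_pos <- which(p1$mask | p2$mask)

  build <- function(levels) {
    g <- g1
    for (f in which(levels == 2L)) g[groups[[f]]] <- g2[groups[[f]]]
    ch <- genes_to_chromosome(g, m)
    if (!is.null(r)) ch$mask <- repair_mask(ch$mask, r, diff_mask_pos, union_pos)
    ch
  }

  cands <- lapply(seq_len(nrow(oa)), function(j) build(oa[j, ]))
  fits <- vapply(cands, function(ch) safe_fitness(fitness_fn, ch), numeric(1))

  # main effect of each factor at each level; child1 takes the better level
  best_levels <- vapply(seq_len(n_fac), function(f) {
    if (mean(fits[oa[, f] == 1L]) >= mean(fits[oa[, f] == 2L])) 1L else 2L
  }, integer(1))
  child1 <- build(best_levels)
  f1 <- safe_fitness(fitness_fn, child1)
  jbest <- which.max(fits)
  list(children = list(child1, cands[[jbest]]), fitness = c(f1, fits[jbest]))
}

safe_fitness <- function(fitness_fn, ch) {
  f <- tryCatch(fitness_fn(ch), error = function(e) {
    message("fitness evaluation failed, scoring 0: ", conditionMessage(e))
    0
  })
  if (!is.finite(f)) 0 else f
}

#' Swap mutation
#'
#' With probability `p_m` the mask undergoes one swap (a uniformly chosen set
#' bit is cleared and a uniformly chosen clear bit is set), preserving the
#' popcount; independently, each of the eight hyperparameter bits flips with
#' probability `p_m`.
#'
#' @param ch Chromosome.
#' @param p_m Mutation probability.
#' @return The (possibly) mutated chromosome.
#' @export
mutate_chromosome <- function(ch, p_m) {
  if (p_m > 0 && stats::runif(1) < p_m) {
    on <- which(ch$mask)
    off <- which(!ch$mask)
    if (length(on) >= 1 && length(off) >= 1) {
      ch$mask[if (length(on) == 1) on else sample(on, 1)] <- FALSE
      ch$mask[if (length(off) == 1) off else sample(off, 1)] <- TRUE
    }
  }
  if (p_m > 0) {
    cb <- int_to_bits(ch$c_code)
    gb <- int_to_bits(ch$g_code)
    flip <- stats::runif(8) < p_m
    ch$c_code <- bits_to_int(xor(cb, flip[1:4]))
    ch$g_code <- bits_to_int(xor(gb, flip[5:8]))
  }
  ch
}

#' Evolve one subset-size stage
#'
#' Runs `g_max` generations of evaluate / tournament-select / orthogonal-array
#' crossover / mutate at fixed popcount `r`, with elitism: the best individual
#' of each generation is carried over unchanged and never mutated, so the
#' best-so-far fitness is non-decreasing.
#'
#' @param pop Population (all individuals at popcount `r`).
#' @param r Current subset size.
#' @param cfg A [ga_config()].
#' @param fitness_fn Chromosome-to-fitness function.
#' @return List with `population`, `best` chromosome, `best_fitness` and the
#'   per-generation best-so-far `trace`.
#' @export
evolve_stage <- function(pop, r, cfg, fitness_fn) {
  stopifnot(all(vapply(pop, popcount, 0L) == r))
  fits <- vapply(pop, function(ch) safe_fitness(fitness_fn, ch), numeric(1))
  n_pop <- length(pop)
  trace <- numeric(cfg$g_max)
  for (g in seq_len(cfg$g_max)) {
    bi <- which.max(fits)
    newpop <- vector("list", n_pop)
    newfits <- numeric(n_pop)
    newpop[[1]] <- pop[[bi]]  # elite: copied unchanged, never mutated
    newfits[1] <- fits[bi]
    pos <- 2L
    while (pos <= n_pop) {
      i <- tournament_select(fits, cfg$tournament_size)
      j <- tournament_select(fits, cfg$tournament_size)
      if (stats::runif(1) < cfg$p_c) {
        cr <- oa_crossover(pop[[i]], pop[[j]], fitness_fn, r = r,
                           max_factors = cfg$oa_max_factors)
        kids <- cr$children
        kfits <- cr$fitness
      } else {
        kids <- list(pop[[i]], pop[[j]])
        kfits <- fits[c(i, j)]
      }
      for (k in 1:2) {
        if (pos > n_pop) break
        mk <- mutate_chromosome(kids[[k]], cfg$p_m)
        newpop[[pos]] <- mk
        newfits[pos] <- if (identical(mk, kids[[k]])) kfits[k]
                        else safe_fitness(fitness_fn, mk)
        pos <- pos + 1L
      }
    }
    pop <- newpop
    fits <- newfits
    stopifnot(all(vapply(pop, popcount, 0L) == r))  # popcount invariant
    trace[g] <- max(fits)
  }
  bi <- which.max(fits)
  list(population = pop, best = pop[[bi]], best_fitness = fits[bi],
       trace = trace)
}

#' Inheritance step
#'
#' Sets one uniformly chosen clear mask bit per individual (popcount grows
#' from `r` to `r + 1`); hyperparameter codes are untouched. An individual
#' with no clear bits passes through unchanged with a message.
#'
#' @param pop Population at popcount `r`.
#' @return Population at popcount `r + 1`.
#' @export
inherit_population <- function(pop) {
  lapply(pop, function(ch) {
    off <- which(!ch$mask)
    if (length(off) == 0) {
      message("inherit: individual already has all bits set; passed through")
      return(ch)
    }
    ch$mask[if (length(off) == 1) off else sample(off, 1)] <- TRUE
    ch
  })
}

#' Run the IBCGA engine on an arbitrary fitness function
#'
#' The search sweeps subset sizes `r_start..r_end`; each stage evolves for
#' `g_max` generations, the best chromosome per stage is recorded, and the
#' inheritance step grows every individual by one feature. Fitness values are
#' cached per distinct chromosome. The global solution maximizes fitness over
#' all stages, ties broken toward smaller `r`.
#'
#' @param m Number of mask bits (features).
#' @param cfg A [ga_config()]; `cfg$seed` fixes the whole run.
#' @param fitness_fn Chromosome-to-fitness function (maximized).
#' @return List with `best` chromosome, `fitness`, `per_r_best` (data.frame
#'   of `r`, `fitness`), `n_evals` (distinct fitness evaluations) and `seed`.
#' @export
ibcga_engine <- function(m, cfg, fitness_fn) {
  stopifnot(inherits(cfg, "ga_config"), m >= cfg$r_end)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  n_evals <- 0L
  cached_fn <- function(ch) {
    key <- chromosome_key(ch)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    n_evals <<- n_evals + 1L
    val <- fitness_fn(ch)
    cache[[key]] <- val
    val
  }
  local_rng(cfg$seed, {
    pop <- init_population(cfg, m)
    rs <- cfg$r_start:cfg$r_end
    stage_best <- vector("list", length(rs))
    stage_fit <- numeric(length(rs))
    for (si in seq_along(rs)) {
      st <- evolve_stage(pop, rs[si], cfg, cached_fn)
      stage_best[[si]] <- st$best
      stage_fit[si] <- st$best_fitness
      pop <- st$population
      if (rs[si] < cfg$r_end) pop <- inherit_population(pop)
    }
    gi <- which.max(stage_fit)  # first max = smallest r on ties
    list(best = stage_best[[gi]], fitness = stage_fit[gi],
         per_r_best = data.frame(r = rs, fitness = stage_fit),
         n_evals = n_evals, seed = cfg$seed)
  })
}

#' Run one IBCGA feature-selection run on an expression dataset
#'
#' Wires the engine to the cross-validated SVM accuracy fitness: a
#' chromosome's fitness is the pooled k-fold CV accuracy of an RBF-SVM
#' trained on its selected features at its encoded `(C, gamma)`.
#'
#' @param ds A labeled [expression_dataset()].
#' @param cfg A [ga_config()].
#' @param split Optional `cv_split`; by default stratified `cv_folds` folds
#'   are built from `cfg$seed`.
#' @param cv_folds Number of CV folds when `split` is not supplied.
#' @param class_weights Optional named class weights for the SVM.
#' @return An object of class `signature_run`: list with `selected_features`,
#'   `params` ([svm_params()]), `fitness`, `per_r_best`, `n_evals`, `seed`
#'   and the raw `mask`.
#' @export
run_ibcga <- function(ds, cfg, split = NULL, cv_folds = 10L,
                      class_weights = NULL) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(cfg, "ga_config"))
  if (is.null(ds$labels)) stop("dataset must be labeled")
  if (nlevels(droplevels(ds$labels)) < 2) stop("both classes must be present")
  if (is.null(split))
    split <- stratified_folds(ds$labels, cv_folds, seed = cfg$seed)
  x <- ds$values
  y <- ds$labels
  fold <- split$fold
  fitness_fn <- function(ch) {
    pooled_cv_accuracy(x, which(ch$mask), y, fold,
                       C_GRID[ch$c_code + 1L], GAMMA_GRID[ch$g_code + 1L],
                       class_weights)
  }
  eng <- ibcga_engine(ncol(x), cfg, fitness_fn)
  params <- decode_params(eng$best$c_code, eng$best$g_code)
  structure(list(selected_features = ds$feature_ids[eng$best$mask],
                 params = params, fitness = eng$fitness,
                 per_r_best = eng$per_r_best, n_evals = eng$n_evals,
                 seed = cfg$seed, mask = eng$best$mask),
            class = "signature_run")
}

#' @export
print.signature_run <- function(x, ...) {
  cat(sprintf("signature_run: %d features, CV accuracy %.4f, C = %g, gamma = %g, seed %d\n",
              length(x$selected_features), x$fitness, x$params$C,
              x$params$gamma, x$seed))
  invisible(x)
}

#' Serialize / read a signature run
#'
#' Structured JSON record (feature ids, hyperparameters, fitness, per-stage
#' trace, seed) for downstream consolidation and audit.
#'
#' @param run A `signature_run`.
#' @param path File path.
#' @return `path` invisibly; `read_signature_run` returns a `signature_run`.
#' @export
write_signature_run <- function(run, path) {
  stopifnot(inherits(run, "signature_run"))
  obj <- list(selected_features = run$selected_features,
              C = run$params$C, gamma = run$params$gamma,
              fitness = run$fitness, per_r_best = run$per_r_best,
              n_evals = run$n_evals, seed = run$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature_run
#' @export
read_signature_run <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(selected_features = obj$selected_features,
                 params = svm_params(obj$C, obj$gamma),
                 fitness = obj$fitness,
                 per_r_best = as.data.frame(obj$per_r_best),
                 n_evals = obj$n_evals, seed = obj$seed, mask = NULL),
            class = "signature_run")
}
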