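#' SVM fitness configuration
#'
#' The wrapper scores candidate gene subsets by the stratified k-fold
#' cross-validated accuracy of a polynomial-kernel support vector machine
#' (fitted with \pkg{e1071}).  Degree 1 with cost 1 — a plain linear
#' machine, the polynomial family's simplest member — is the default; both
#' are configurable.  Features are standardised inside each training fold
#' (training-fold mean/sd applied to the held-out fold) so fitness does not
#' depend on the expression scale.
#'
#' @param degree Polynomial degree (>= 1).
#' @param cost Regularisation constant C (> 0).
#' @param cv_folds Cross-validation folds (default 10).
#' @param cv_seed Seed for the fold shuffle; one fixed assignment is used
#'   for a whole swarm run so all particles are scored on identical splits.
#' @return An `svm_config` list.
#' @export
svm_config <- function(degree = 1L, cost = 1, cv_folds = 10L, cv_seed = 1L) {
  if (degree < 1) stop("degree must be >= 1")
  if (cost <= 0) stop("cost must be > 0")
  structure(list(degree = as.integer(degree), cost = cost,
                 cv_folds = as.integer(cv_folds),
                 cv_seed = as.integer(cv_seed)),
            class = "svm_config")
}

#' Swarm configuration for geometric binary PSO
#'
#' @param population Number of particles (>= 2, default 20).
#' @param iterations Iteration cap (default 100).
#' @param w_self,w_pbest,w_gbest Non-negative crossover weights summing
#'   to 1: the probability that each offspring bit is copied from the
#'   particle's current position, its personal best, or the global best.
#' @param mutation_rate Per-bit flip probability after crossover; `NULL`
#'   (default) means `1/L` for mask length `L`.
#' @param init_inclusion_prob Probability that a gene is included in an
#'   initial particle (default 0.5).
#' @param stall_iterations Optional early stop: halt when the global best
#'   has not improved for this many iterations (`Inf` disables, default).
#' @param seed Integer seed for the swarm's randomness.
#' @param svm An [svm_config] for the fitness function.
#' @return A `gbpso_config` list.
#' @export
gbpso_config <- function(population = 20L, iterations = 100L,
                         w_self = 1 / 3, w_pbest = 1 / 3, w_gbest = 1 / 3,
                         mutation_rate = NULL, init_inclusion_prob = 0.5,
                         stall_iterations = Inf, seed = 1L,
                         svm = svm_config()) {
  if (population < 2) stop("population must be >= 2")
  w <- c(w_self, w_pbest, w_gbest)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("crossover weights must be non-negative and sum to 1")
  if (!is.null(mutation_rate) &&
      (mutation_rate < 0 || mutation_rate > 1))
    stop("mutation_rate must be in [0, 1]")
  if (init_inclusion_prob < 0 || init_inclusion_prob > 1)
    stop("init_inclusion_prob must be in [0, 1]")
  structure(list(population = as.integer(population),
                 iterations = as.integer(iterations),
                 w_self = w_self, w_pbest = w_pbest, w_gbest = w_gbest,
                 mutation_rate = mutation_rate,
                 init_inclusion_prob = init_inclusion_prob,
                 stall_iterations = stall_iterations,
                 seed = as.integer(seed), svm = svm),
            class = "gbpso_config")
}

# Per-fold confusion counts of the masked SVM under stratified CV.
# Returns a folds x 4 matrix (TP, TN, FP, FN); positive class = label 1.
cv_confusion <- function(ds, mask, svm_cfg, fold_seed = svm_cfg$cv_seed,
                         positive_class = 1L) {
  mask <- as.logical(mask)
  if (length(mask) != length(ds$gene_ids))
    stop("mask length must equal gene count")
  X <- t(ds$values[mask, , drop = FALSE])       # samples x selected genes
  y <- factor(ds$labels, levels = c(0L, 1L))
  fold <- suppressWarnings(make_folds(ds$labels, svm_cfg$cv_folds, fold_seed))
  k <- attr(fold, "k")
  counts <- matrix(0L, k, 4, dimnames = list(NULL, c("TP", "TN", "FP", "FN")))
  for (i in seq_len(k)) {
    tr <- fold != i
    mu <- colMeans(X[tr, , drop = FALSE])
    sdev <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sdev[sdev == 0] <- 1
    Xtr <- scale(X[tr, , drop = FALSE], mu, sdev)
    Xte <- scale(X[!tr, , drop = FALSE], mu, sdev)
    fit <- e1071::svm(Xtr, y[tr], kernel = "polynomial",
                      degree = svm_cfg$degree, gamma = 1 / ncol(Xtr),
                      coef0 = 0, cost = svm_cfg$cost, scale = FALSE)
    pred <- predict(fit, Xte)
    truth <- y[!tr]
    pos <- as.character(positive_class)
    counts[i, "TP"] <- sum(pred == pos & truth == pos)
    counts[i, "TN"] <- sum(pred != pos & truth != pos)
    counts[i, "FP"] <- sum(pred == pos & truth != pos)
    counts[i, "FN"] <- sum(pred != pos & truth == pos)
  }
  counts
}

#' Cross-validated fitness of a gene subset
#'
#' Mean per-fold accuracy of the polynomial-kernel SVM trained on the genes
#' where the mask is 1, under stratified k-fold cross-validation with the
#' configuration's fixed fold seed.  The empty mask scores 0 by convention.
#'
#' @param mask Logical or 0/1 vector over the dataset's genes.
#' @param ds An [expression_dataset].
#' @param svm An [svm_config].
#' @return Accuracy as a fraction in `[0, 1]`.
#' @export
subset_fitness <- function(mask, ds, svm = svm_config()) {
  mask <- as.logical(mask)
  if (length(mask) != length(ds$gene_ids))
    stop("mask length must equal gene count")
  if (!any(mask)) return(0)
  counts <- cv_confusion(ds, mask, svm)
  mean(rowSums(counts[, c("TP", "TN"), drop = FALSE]) / rowSums(counts))
}

#' One geometric-PSO position update
#'
#' The geometric binary PSO replaces the velocity update of real-valued PSO
#' with a three-parent crossover in Hamming space: each offspring bit is
#' copied from the particle's current position, personal best, or global
#' best with probabilities `(w_self, w_pbest, w_gbest)`, then flipped
#' independently with probability `mutation_rate`.  With zero mutation the
#' offspring always lies in the parents' Hamming convex hull.
#'
#' @param current,pbest,gbest Equal-length 0/1 vectors.
#' @param cfg A [gbpso_config] (weights and mutation rate are used).
#' @return A 0/1 integer vector.  Consumes the R random number stream.
#' @export
gbpso_move <- function(current, pbest, gbest, cfg = gbpso_config()) {
  L <- length(current)
  if (length(pbest) != L || length(gbest) != L)
    stop("masks must have equal length")
  mu <- cfg$mutation_rate %||% (1 / L)
  parents <- rbind(as.integer(current), as.integer(pbest), as.integer(gbest))
  pick <- sample.int(3L, L, replace = TRUE,
                     prob = c(cfg$w_self, cfg$w_pbest, cfg$w_gbest))
  child <- parents[cbind(pick, seq_len(L))]
  flip <- stats::runif(L) < mu
  child[flip] <- 1L - child[flip]
  child
}

# Preference order over (fitness, mask) pairs: higher fitness, then fewer
# selected genes, then lexicographically smaller mask.
mask_better <- function(fit_a, mask_a, fit_b, mask_b) {
  if (fit_a != fit_b) return(fit_a > fit_b)
  sa <- sum(mask_a); sb <- sum(mask_b)
  if (sa != sb) return(sa < sb)
  d <- which(mask_a != mask_b)
  length(d) > 0 && mask_a[d[1]] < mask_b[d[1]]
}

#' Run the GBPSO-SVM wrapper
#'
#' Initialises `population` particles with independent per-gene inclusion
#' probability, scores each with [subset_fitness()], and iterates
#' [gbpso_move()] with personal-best and global-best bookkeeping.  Fitness
#' values are cached by mask, so revisited subsets cost nothing.  Ties in
#' fitness are resolved toward fewer genes, then the lexicographically
#' smaller mask.  Fully reproducible under `cfg$seed`.
#'
#' @param ds_filtered An [expression_dataset], typically the top-n output of
#'   [select_top()].
#' @param cfg A [gbpso_config].
#' @return A `selection_result` list: `best_mask`, `best_fitness`,
#'   `fitness_trace` (global best after initialisation and after each
#'   iteration; non-decreasing), `selected_gene_ids`, `n_evaluations`.
#' @export
run_gbpso <- function(ds_filtered, cfg = gbpso_config()) {
  L <- length(ds_filtered$gene_ids)
  if (L == 0L) stop("filtered dataset has no genes")

  cache <- new.env(parent = emptyenv())
  evals <- 0L
  fitness_of <- function(mask) {
    key <- paste(mask, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- subset_fitness(mask, ds_filtered, cfg$svm)
    evals <<- evals + 1L
    cache[[key]] <- f
    f
  }

  withr::with_seed(cfg$seed, {
    pop <- matrix(as.integer(stats::runif(cfg$population * L) <
                               cfg$init_inclusion_prob),
                  cfg$population, L)
    fit <- apply(pop, 1, fitness_of)
    pbest <- pop
    pbest_fit <- fit
    gi <- 1L
    for (p in seq_len(cfg$population))
      if (mask_better(fit[p], pop[p, ], fit[gi], pop[gi, ])) gi <- p
    gbest <- pop[gi, ]
    gbest_fit <- fit[gi]

    trace <- numeric(cfg$iterations + 1L)
    trace[1L] <- gbest_fit
    stall <- 0L
    it_done <- 0L
    for (it in seq_len(cfg$iterations)) {
      improved <- FALSE
      for (p in seq_len(cfg$population)) {
        pop[p, ] <- gbpso_move(pop[p, ], pbest[p, ], gbest, cfg)
        f <- fitness_of(pop[p, ])
        if (mask_better(f, pop[p, ], pbest_fit[p], pbest[p, ])) {
          pbest[p, ] <- pop[p, ]
          pbest_fit[p] <- f
        }
        if (mask_better(f, pop[p, ], gbest_fit, gbest)) {
          improved <- improved || f > gbest_fit
          gbest <- pop[p, ]
          gbest_fit <- f
        }
      }
      it_done <- it
      trace[it + 1L] <- gbest_fit
      stall <- if (improved) 0L else stall + 1L
      if (stall >= cfg$stall_iterations) break
    }
    trace <- trace[seq_len(it_done + 1L)]
  })

  structure(list(best_mask = as.integer(gbest), best_fitness = gbest_fit,
                 fitness_trace = trace,
                 selected_gene_ids = ds_filtered$gene_ids[gbest == 1L],
                 n_evaluations = evals),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", length(x$selected_gene_ids), " genes selected, ",
      "CV fitness ", sprintf("%.4f", x$best_fitness), "\n", sep = "")
  cat("  iterations: ", length(x$fitness_trace) - 1L,
      "; distinct subsets evaluated: ", x$n_evaluations, "\n", sep = "")
  invisible(x)
}

#' Write a swarm fitness trace as TSV
#'
#' @param result A `selection_result`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fitness_trace <- function(result, path) {
  utils::write.table(
    data.frame(iteration = seq_along(result$fitness_trace) - 1L,
               best_fitness = result$fitness_trace),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
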