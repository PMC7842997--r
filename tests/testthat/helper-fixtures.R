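# Small dataset builders shared across test files.

# Deterministic toy dataset: `g1` separates the classes perfectly, `g2` is
# constant.
toy_ds <- function() {
  expression_dataset(
    values = rbind(g1 = c(1, 2, 1.5, 8, 9, 8.5),
                   g2 = rep(5, 6)),
    gene_ids = c("g1", "g2"),
    sample_ids = paste0("S", 1:6),
    labels = c(0L, 0L, 0L, 1L, 1L, 1L))
}

# Random positive-valued dataset with no structure.
rand_ds <- function(n_genes, n_per_class, seed) {
  withr::with_seed(seed, {
    v <- matrix(rlnorm(n_genes * 2 * n_per_class, log(100), 0.2),
                n_genes, 2 * n_per_class)
  })
  expression_dataset(v, sprintf("g%03d", seq_len(n_genes)),
                     paste0("S", seq_len(2 * n_per_class)),
                     rep(c(0L, 1L), each = n_per_class))
}

# Perfectly separable one-strong-gene dataset plus noise genes.
separable_ds <- function(n_noise = 0, n_per_class = 20, seed = 1) {
  withr::with_seed(seed, {
    strong <- c(rnorm(n_per_class, 0, 0.05), rnorm(n_per_class, 1, 0.05))
    v <- rbind(strong,
               if (n_noise > 0)
                 matrix(rnorm(n_noise * 2 * n_per_class), n_noise))
  })
  expression_dataset(v, paste0("g", seq_len(n_noise + 1)),
                     paste0("S", seq_len(2 * n_per_class)),
                     rep(c(0L, 1L), each = n_per_class))
}

# Independent re-implementation of the pair-count statistic (double loop).
oracle_wrs <- function(x0, x1) {
  s <- 0L
  for (i in seq_along(x0))
    for (j in seq_along(x1))
      if (x1[j] - x0[i] <= 0) s <- s + 1L
  list(s = s, q = max(s, length(x0) * length(x1) - s))
}

# Exhaustive best subset fitness over all non-empty masks of a small dataset.
oracle_best_subset <- function(ds, svm) {
  L <- length(ds$gene_ids)
  best <- 0
  for (code in seq_len(2^L - 1)) {
    mask <- as.integer(intToBits(code)[1:L])
    f <- subset_fitness(mask, ds, svm)
    if (f > best) best <- f
  }
  best
}
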