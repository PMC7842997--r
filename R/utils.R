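# Internal helpers shared across stages.

# Stratified fold assignment: every class is shuffled under `seed` and dealt
# round-robin into k folds, so each fold holds roughly class-proportional
# counts.  If the smaller class has fewer than k samples, k is reduced to
# that size with a warning (a fold must not exhaust a class from the
# training split).
make_folds <- function(labels, k, seed) {
  k <- as.integer(k)
  if (k < 2L) stop("at least 2 folds required")
  min_class <- min(tabulate(labels + 1L, 2L))
  if (min_class < k) {
    warning("reducing folds from ", k, " to ", min_class,
            " (smallest class has only ", min_class, " samples)")
    k <- min_class
  }
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  attr(fold, "k") <- k
  fold
}

# Derive independent per-stage seeds from one master seed.  Kept below
# .Machine$integer.max so they remain valid set.seed() inputs.
derive_seeds <- function(master, n, names = NULL) {
  s <- withr::with_seed(as.integer(master),
                        sample.int(.Machine$integer.max - 1L, n))
  if (!is.null(names)) names(s) <- names
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
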