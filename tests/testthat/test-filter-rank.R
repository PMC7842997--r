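test_that("welch_t evaluates the unequal-variance statistic", {
  r <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3 / sqrt(2 / 3))
  expect_equal(r$score, abs(r$t))
  expect_equal(unlist(r[c("n", "m")]), c(n = 3, m = 3))

  # identical samples -> t = 0; class swap negates t, |t| unchanged
  expect_equal(welch_t(c(2, 5, 9), c(2, 5, 9))$t, 0)
  a <- welch_t(c(1, 4, 2), c(7, 8, 6))
  b <- welch_t(c(7, 8, 6), c(1, 4, 2))
  expect_equal(a$t, -b$t)
  expect_equal(a$score, b$score)

  # degenerate spread: equal constant vectors -> 0; unequal -> flagged Inf
  expect_equal(welch_t(c(3, 3), c(3, 3))$t, 0)
  d <- welch_t(c(3, 3), c(4, 4))
  expect_true(is.infinite(d$score) && d$degenerate)
})

test_that("welch_t agrees with stats::t.test on random instances", {
  for (seed in 1:100) {
    withr::with_seed(seed, {
      x <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
      y <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2))
    })
    ref <- t.test(x, y)           # Welch by default
    r <- welch_t(x, y)
    expect_equal(r$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$p, ref$p.value, tolerance = 1e-10)
    expect_equal(r$df, unname(ref$parameter), tolerance = 1e-10)
  }
})

test_that("|t| is invariant under joint positive affine transforms", {
  withr::with_seed(3, {x <- rnorm(8); y <- rnorm(10, 1)})
  base <- welch_t(x, y)$score
  expect_equal(welch_t(2.5 * x + 7, 2.5 * y + 7)$score, base)
  expect_equal(welch_t(0.1 * x - 3, 0.1 * y - 3)$score, base)
})

test_that("wrs_score counts pairs with ties included and is swap-symmetric", {
  expect_equal(wrs_score(c(1, 3), c(2, 4))[c("s", "q")], list(s = 1, q = 3))
  expect_equal(wrs_score(c(1), c(1))$s, 1)                 # tie counts
  r <- wrs_score(c(1, 2, 3), c(10, 11))                    # full separation
  expect_equal(r$s, 0)
  expect_equal(r$q, 6)
  # q invariant under class swap (no ties)
  withr::with_seed(5, {x0 <- runif(6); x1 <- runif(7)})
  expect_equal(wrs_score(x0, x1)$q, wrs_score(x1, x0)$q)
  # s + s_swapped == N0*N1 when no ties
  expect_equal(wrs_score(x0, x1)$s + wrs_score(x1, x0)$s, 42)
})

test_that("wrs_score matches exhaustive pair enumeration", {
  for (seed in 1:300) {
    withr::with_seed(seed, {
      n0 <- sample(1:8, 1); n1 <- sample(1:8, 1)
      x0 <- sample(1:5, n0, replace = TRUE)   # integer-valued: many ties
      x1 <- sample(1:5, n1, replace = TRUE)
    })
    got <- wrs_score(x0, x1)
    want <- oracle_wrs(x0, x1)
    expect_equal(got$s, want$s)
    expect_equal(got$q, want$q)
  }
})

test_that("k-fold global weights equal brute-force fold-rank summation", {
  ds <- rand_ds(n_genes = 100, n_per_class = 15, seed = 11)
  for (filt in c("tt", "wrs")) {
    tab <- kfold_filter_weights(ds, filt, k = 10, seed = 4)
    fold <- hidimsel:::make_folds(ds$labels, 10, 4)
    # independent recomputation: per-fold scores -> Borda weights -> sum
    w_oracle <- rep(0, 100)
    for (i in 1:10) {
      tr <- fold != i
      sc <- vapply(seq_len(100), function(g) {
        x <- ds$values[g, tr & ds$labels == 0L]
        y <- ds$values[g, tr & ds$labels == 1L]
        if (filt == "tt") welch_t(x, y)$score else wrs_score(x, y)$q
      }, numeric(1))
      w_oracle <- w_oracle + (100 - rank(-sc, ties.method = "average") + 1)
    }
    expect_equal(tab$weight, w_oracle)
    expect_setequal(tab$rank, 1:100)
  }
})

test_that("K = 1 degenerates to the plain single-run filter ranking", {
  ds <- rand_ds(n_genes = 40, n_per_class = 6, seed = 2)
  tab <- kfold_filter_weights(ds, "tt", k = 1)
  sc <- vapply(seq_len(40), function(g)
    welch_t(ds$values[g, ds$labels == 0L], ds$values[g, ds$labels == 1L])$score,
    numeric(1))
  expect_equal(tab$weight, 40 - rank(-sc, ties.method = "average") + 1)
  expect_equal(order(tab$rank), order(-sc, ds$gene_ids))
})

test_that("a planted large-effect gene attains rank 1 under both filters", {
  sp <- synthetic_spec(n_genes = 100, n_samples_per_class = 15,
                       n_informative = 1, effect_size = 4, seed = 21)
  gen <- make_dataset(sp)
  for (filt in c("tt", "wrs")) {
    tab <- kfold_filter_weights(gen$dataset, filt, k = 10, seed = 8)
    expect_equal(tab$gene_id[tab$rank == 1L], gen$informative)
  }
})

test_that("permuting gene order permutes the score table identically", {
  ds <- rand_ds(n_genes = 30, n_per_class = 10, seed = 6)
  perm <- withr::with_seed(7, sample(30))
  ds_perm <- expression_dataset(ds$values[perm, ], ds$gene_ids[perm],
                                ds$sample_ids, ds$labels)
  a <- kfold_filter_weights(ds, "tt", k = 5, seed = 3)
  b <- kfold_filter_weights(ds_perm, "tt", k = 5, seed = 3)
  m <- match(a$gene_id, b$gene_id)
  expect_equal(b$weight[m], a$weight)
  expect_equal(b$rank[m], a$rank)
})

test_that("combine_tt_wrs averages min-max-normalised weights", {
  mk <- function(ids, w) {
    ord <- order(-w, ids); r <- integer(length(w)); r[ord] <- seq_along(w)
    structure(data.frame(gene_id = ids, weight = w, rank = r,
                         stringsAsFactors = FALSE),
              class = c("gene_score_table", "data.frame"))
  }
  ids <- paste0("g", 1:5)
  a <- mk(ids, c(10, 8, 6, 4, 2))
  b <- mk(ids, c(1, 5, 2, 9, 3))
  cmb <- combine_tt_wrs(a, b)
  # hand-computed normalised mean: a -> (1,.75,.5,.25,0); b -> (0,.5,.125,1,.25)
  want <- (c(1, .75, .5, .25, 0) + c(0, .5, .125, 1, .25)) / 2
  expect_equal(cmb$weight, want)                      # .5 .625 .3125 .625 .125
  expect_equal(cmb$gene_id[order(cmb$rank)], c("g2", "g4", "g1", "g3", "g5"))

  # identical rankings are preserved
  expect_equal(combine_tt_wrs(a, a)$rank, a$rank)
  # a constant table contributes nothing: combined order = other table's order
  const <- mk(ids, rep(7, 5))
  expect_equal(combine_tt_wrs(const, b)$rank, b$rank)
  expect_error(combine_tt_wrs(a, mk(paste0("h", 1:5), 1:5)), "same gene set")
})

test_that("select_top keeps the n best genes with cap and tie rules", {
  ds <- rand_ds(n_genes = 5, n_per_class = 3, seed = 1)
  ds$gene_ids <- paste0("g", 1:5)
  dimnames(ds$values)[[1]] <- ds$gene_ids
  tab <- structure(data.frame(gene_id = paste0("g", 1:5),
                              weight = c(5, 9, 9, 1, 7),
                              rank = c(4L, 1L, 2L, 5L, 3L)),
                   class = c("gene_score_table", "data.frame"))
  top <- select_top(tab, ds, 3)
  expect_equal(top$gene_ids, c("g2", "g3", "g5"))
  expect_equal(select_top(tab, ds, 5)$gene_ids, tab$gene_id[order(tab$rank)])
  expect_warning(all5 <- select_top(tab, ds, 200), "only 5")
  expect_length(all5$gene_ids, 5L)
  expect_error(select_top(tab, ds, 0), ">= 1")
})

test_that("doubling every fold weight doubles w(f) and preserves ranking", {
  ds <- rand_ds(n_genes = 25, n_per_class = 8, seed = 13)
  tab <- kfold_filter_weights(ds, "wrs", k = 5, seed = 2)
  fold_cols <- grep("^w\\d+$", names(tab))
  expect_equal(unname(rowSums(tab[fold_cols])), tab$weight)  # additivity
  doubled <- rowSums(2 * tab[fold_cols])
  expect_equal(order(-doubled, tab$gene_id), order(-tab$weight, tab$gene_id))
})
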