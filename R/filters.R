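#' Welch two-sample t statistic for one gene
#'
#' Unequal-variance t statistic
#' \deqn{t = (c_1 - c_2) / \sqrt{\sigma_1^2/n + \sigma_2^2/m}}
#' with sample variances, plus the two-sided p-value from the t reference
#' distribution with Welch-Satterthwaite degrees of freedom.  The filter
#' score used for ranking is `|t|`.
#'
#' Degenerate spread (both variances zero) gives `t = 0` when the means are
#' equal and an infinite score (flagged via `degenerate = TRUE`) otherwise.
#'
#' @param x,y Numeric vectors (class 1 and class 2), each of length >= 2.
#' @return A `tt_result` list: `t`, `p`, `df`, `c1`, `c2`, `var1`, `var2`,
#'   `n`, `m`, `score`, `degenerate`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))$t   # -3 / sqrt(2/3)
welch_t <- function(x, y) {
  n <- length(x); m <- length(y)
  if (n < 2L || m < 2L) stop("each class needs at least 2 values")
  c1 <- mean(x); c2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n + v2 / m
  degenerate <- FALSE
  if (se2 == 0) {
    if (c1 == c2) {
      t <- 0; p <- 1; df <- n + m - 2
    } else {
      t <- sign(c1 - c2) * Inf; p <- 0; df <- n + m - 2
      degenerate <- TRUE
    }
  } else {
    t <- (c1 - c2) / sqrt(se2)
    df <- se2^2 / ((v1 / n)^2 / (n - 1) + (v2 / m)^2 / (m - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(t = t, p = p, df = df, c1 = c1, c2 = c2, var1 = v1,
                 var2 = v2, n = n, m = m, score = abs(t),
                 degenerate = degenerate),
            class = "tt_result")
}

#' Wilcoxon rank-sum pair count and gene importance
#'
#' Counts, over all `N0 x N1` cross-class sample pairs, how often the
#' class-1 value does not exceed the class-0 value:
#' \deqn{s(g) = \sum_{i \in N_0} \sum_{j \in N_1} I(x_j(g) - x_i(g) \le 0)}
#' A gene separates the classes when `s` is near 0 or near `N0*N1`, so the
#' importance used as the filter score is `q(g) = max(s, N0*N1 - s)`.
#'
#' @param x0,x1 Non-empty numeric vectors for class 0 and class 1.
#' @return A `wrs_result` list: `s`, `q`, `N0`, `N1`.
#' @export
#' @examples
#' wrs_score(c(1, 3), c(2, 4))   # s = 1, q = 3
wrs_score <- function(x0, x1) {
  if (!length(x0) || !length(x1)) stop("both classes must be non-empty")
  s <- sum(outer(x1, x0, `-`) <= 0)
  n0 <- length(x0); n1 <- length(x1)
  structure(list(s = s, q = max(s, n0 * n1 - s), N0 = n0, N1 = n1),
            class = "wrs_result")
}

# Vectorised per-gene filter scores on a genes x samples matrix.
filter_scores <- function(values, labels, filter = c("tt", "wrs")) {
  filter <- match.arg(filter)
  i1 <- labels == 0L; i2 <- labels == 1L
  if (filter == "tt") {
    x <- values[, i1, drop = FALSE]; y <- values[, i2, drop = FALSE]
    n <- ncol(x); m <- ncol(y)
    c1 <- rowMeans(x); c2 <- rowMeans(y)
    v1 <- rowSums((x - c1)^2) / (n - 1)
    v2 <- rowSums((y - c2)^2) / (m - 1)
    se2 <- v1 / n + v2 / m
    sc <- abs(c1 - c2) / sqrt(se2)
    sc[se2 == 0] <- ifelse(c1[se2 == 0] == c2[se2 == 0], 0, Inf)
    sc
  } else {
    x0 <- values[, i1, drop = FALSE]; x1 <- values[, i2, drop = FALSE]
    half <- ncol(x0) * ncol(x1)
    vapply(seq_len(nrow(values)), function(g) {
      s <- sum(outer(x1[g, ], x0[g, ], `-`) <= 0)
      max(s, half - s)
    }, numeric(1))
  }
}

#' Rank genes with a statistical filter in a k-fold run
#'
#' Builds `k` stratified folds; on each fold's training portion (all samples
#' except that fold) every gene receives a filter score, converted to a
#' positional Borda weight `w_i(f) = G - rank_i(f) + 1` (descending-score
#' ranking, average ranks on ties).  The global weight aggregates the folds,
#' \deqn{w(f) = \sum_{i=1}^{K} w_i(f),}
#' and genes are ranked by descending `w(f)`.  Repeating the scoring across
#' folds damps the influence of any single subset of samples on the ranking.
#'
#' @param ds An [expression_dataset].
#' @param filter `"tt"` (Welch t) or `"wrs"` (rank-sum importance).
#' @param k Number of folds (default 10; reduced with a warning when the
#'   smaller class has fewer samples).  `k = 1` scores once on all samples.
#' @param seed Integer seed controlling the fold shuffle.
#' @return A `gene_score_table` data frame: `gene_id`, `weight`, `rank`, and
#'   one `w<i>` column per fold; attributes `filter`, `k`, `seed`.
#' @export
kfold_filter_weights <- function(ds, filter = c("tt", "wrs"), k = 10,
                                 seed = 1L) {
  filter <- match.arg(filter)
  g <- length(ds$gene_ids)
  if (k == 1) {
    fold <- rep(0L, length(ds$labels))   # nothing held out
    attr(fold, "k") <- 1L
  } else {
    fold <- make_folds(ds$labels, k, seed)
  }
  k <- attr(fold, "k")

  fold_w <- matrix(NA_real_, g, k,
                   dimnames = list(ds$gene_ids, paste0("w", seq_len(k))))
  for (i in seq_len(k)) {
    train <- fold != i
    sc <- filter_scores(ds$values[, train, drop = FALSE], ds$labels[train],
                        filter)
    fold_w[, i] <- g - rank(-sc, ties.method = "average") + 1
  }
  weight <- rowSums(fold_w)
  ord <- order(-weight, ds$gene_ids)
  rank_final <- integer(g)
  rank_final[ord] <- seq_len(g)

  tab <- data.frame(gene_id = ds$gene_ids, weight = weight,
                    rank = rank_final, fold_w,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(tab, filter = filter, k = k, seed = seed,
            class = c("gene_score_table", "data.frame"))
}

#' Combine two filter rankings
#'
#' Each table's global weights are min-max normalised to `[0, 1]` (a
#' constant, zero-information table normalises to 0.5 everywhere) and the
#' combined weight is their mean, re-ranked descending.
#'
#' @param table_a,table_b `gene_score_table`s over the same gene universe.
#' @return A `gene_score_table` with columns `gene_id`, `weight`, `rank`,
#'   `norm_a`, `norm_b`.
#' @export
combine_tt_wrs <- function(table_a, table_b) {
  if (!setequal(table_a$gene_id, table_b$gene_id) ||
      nrow(table_a) != nrow(table_b))
    stop("tables must cover the same gene set")
  b <- table_b[match(table_a$gene_id, table_b$gene_id), ]
  norm <- function(w) {
    r <- range(w)
    if (r[1] == r[2]) rep(0.5, length(w)) else (w - r[1]) / (r[2] - r[1])
  }
  na <- norm(table_a$weight); nb <- norm(b$weight)
  weight <- (na + nb) / 2
  ord <- order(-weight, table_a$gene_id)
  rank_final <- integer(length(weight))
  rank_final[ord] <- seq_along(weight)
  tab <- data.frame(gene_id = table_a$gene_id, weight = weight,
                    rank = rank_final, norm_a = na, norm_b = nb,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(tab, filter = "ttwrs",
            class = c("gene_score_table", "data.frame"))
}

#' Restrict a dataset to the top-ranked genes
#'
#' @param table A `gene_score_table`.
#' @param ds The [expression_dataset] the table was computed on.
#' @param n Number of genes to keep (default 200, the tool's standard
#'   filtration size).  Ties in weight are broken by gene id; when `n`
#'   exceeds the gene count all genes are returned with a warning.
#' @return An [expression_dataset] with genes in rank order.
#' @export
select_top <- function(table, ds, n = 200) {
  if (n < 1) stop("n must be >= 1")
  g <- nrow(table)
  if (n > g) {
    warning("requested ", n, " genes but only ", g, " available; keeping all")
    n <- g
  }
  ids <- table$gene_id[order(table$rank)][seq_len(n)]
  subset_genes(ds, ids)
}

#' Write a gene score table as TSV
#'
#' @param table A `gene_score_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_score_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
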