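#' Confusion counts
#'
#' @param TP,TN,FP,FN Non-negative integers.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(as.list(counts), class = "confusion_counts")
}

#' Classification accuracy from confusion counts
#'
#' `(TP + TN) / (TP + TN + FN + FP)`.
#'
#' @param c A [confusion_counts] (or any list with TP/TN/FP/FN).
#' @return A fraction in `[0, 1]`.
#' @export
accuracy <- function(c) {
  total <- c$TP + c$TN + c$FP + c$FN
  if (total <= 0) stop("no evaluated samples")
  (c$TP + c$TN) / total
}

#' Classification precision from confusion counts
#'
#' `TP / (TP + FP)`.  When nothing was predicted positive the quantity is
#' undefined and `NA` is returned (not 0).
#'
#' @param c A [confusion_counts].
#' @return A fraction in `[0, 1]`, or `NA_real_` when `TP + FP == 0`.
#' @export
precision <- function(c) {
  if (c$TP + c$FP == 0) return(NA_real_)
  c$TP / (c$TP + c$FP)
}

#' Evaluate a gene subset with repeated cross-validation
#'
#' Runs `repeats` rounds of stratified k-fold cross-validation of the
#' polynomial-kernel SVM on the masked genes.  Accuracy is reported as the
#' mean of per-fold accuracies with its standard deviation across folds;
#' precision is computed from the pooled confusion counts.  Both are
#' percentages.  With `repeats = 1` and `seed = svm$cv_seed` the accuracy
#' reproduces [subset_fitness()] exactly (identical folds).
#'
#' @param ds An [expression_dataset].
#' @param mask Logical or 0/1 vector over the dataset's genes.
#' @param svm An [svm_config].
#' @param repeats Number of CV repetitions (default 1).
#' @param seed Seed for the first repetition's folds (default the
#'   configuration's `cv_seed`); later repetitions use derived seeds.
#' @param positive_class Label treated as positive for precision (default
#'   1, the second listed class — by convention the disease class).
#' @return An `evaluation_report` list: `accuracy`, `accuracy_sd`,
#'   `precision` (percentages), `counts` (pooled [confusion_counts]),
#'   `fold_counts` (per-fold matrix across repeats), `fold_accuracy`,
#'   `n_selected_genes`, `repeats`, `positive_class`.
#' @export
evaluate_subset <- function(ds, mask, svm = svm_config(), repeats = 1L,
                            seed = svm$cv_seed, positive_class = 1L) {
  mask <- as.logical(mask)
  seeds <- if (repeats == 1L) seed else
    derive_seeds(seed, repeats)
  fold_counts <- do.call(rbind, lapply(seeds, function(s)
    cv_confusion(ds, mask, svm, fold_seed = s,
                 positive_class = positive_class)))
  fold_acc <- rowSums(fold_counts[, c("TP", "TN"), drop = FALSE]) /
    rowSums(fold_counts)
  pooled <- confusion_counts(sum(fold_counts[, "TP"]),
                             sum(fold_counts[, "TN"]),
                             sum(fold_counts[, "FP"]),
                             sum(fold_counts[, "FN"]))
  structure(list(accuracy = 100 * mean(fold_acc),
                 accuracy_sd = 100 * stats::sd(fold_acc),
                 precision = 100 * precision(pooled),
                 counts = pooled,
                 fold_counts = fold_counts,
                 fold_accuracy = fold_acc,
                 n_selected_genes = sum(mask),
                 repeats = repeats,
                 positive_class = positive_class),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$n_selected_genes, " genes\n", sep = "")
  cat(sprintf("  accuracy : %.1f%% ± %.1f\n", x$accuracy, x$accuracy_sd))
  cat(sprintf("  precision: %s\n",
              if (is.na(x$precision)) "n/a (nothing predicted positive)"
              else sprintf("%.1f%%", x$precision)))
  cat("  pooled counts: TP=", x$counts$TP, " TN=", x$counts$TN,
      " FP=", x$counts$FP, " FN=", x$counts$FN, "\n", sep = "")
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  utils::write.table(
    data.frame(metric = c("accuracy_pct", "accuracy_sd_pct", "precision_pct",
                          "TP", "TN", "FP", "FN", "n_selected_genes"),
               value = c(report$accuracy, report$accuracy_sd,
                         report$precision, report$counts$TP,
                         report$counts$TN, report$counts$FP,
                         report$counts$FN, report$n_selected_genes)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expression matrix of selected genes for heatmap display
#'
#' Extracts the selected genes x all samples matrix with samples reordered
#' class 0 first, then class 1 (stable within class), suitable for heatmap
#' rendering of final biomarker subsets.
#'
#' @param ds An [expression_dataset].
#' @param gene_ids Genes to extract; unknown ids raise an error naming them.
#' @param scale_rows If `TRUE`, min-max scale every non-constant row
#'   to `[0, 1]`.
#' @param path Optional TSV output path.
#' @param image Optional PNG output path (rendered with \pkg{pheatmap} when
#'   available; purely cosmetic).
#' @return The matrix, invisibly when `path` is given.
#' @export
heatmap_matrix <- function(ds, gene_ids, scale_rows = FALSE, path = NULL,
                           image = NULL) {
  missing <- setdiff(gene_ids, ds$gene_ids)
  if (length(missing))
    stop("unknown gene id(s): ", paste(missing, collapse = ", "))
  ord <- order(ds$labels)
  m <- ds$values[gene_ids, ord, drop = FALSE]
  colnames(m) <- ds$sample_ids[ord]
  if (scale_rows) {
    for (i in seq_len(nrow(m))) {
      r <- range(m[i, ])
      if (r[1] < r[2]) m[i, ] <- (m[i, ] - r[1]) / (r[2] - r[1])
    }
  }
  if (!is.null(path))
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  if (!is.null(image) && requireNamespace("pheatmap", quietly = TRUE)) {
    grDevices::png(image, width = 900, height = 100 + 40 * nrow(m))
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE)
    grDevices::dev.off()
  }
  if (is.null(path)) m else invisible(m)
}
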