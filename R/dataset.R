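#' Construct an expression dataset
#'
#' The common in-memory container for all stages of the pipeline: a numeric
#' genes x samples matrix together with gene identifiers, sample identifiers
#' and a binary class label per sample.
#'
#' @param values Numeric matrix, genes in rows and samples in columns.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   column.
#' @param labels Integer vector of per-sample class labels in `{0, 1}`.
#' @param class_names Character vector of length 2 giving display names for
#'   class 0 and class 1.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `labels` and `class_names`.
#' @export
#' @examples
#' m <- matrix(1:6, nrow = 2, dimnames = NULL)
#' ds <- expression_dataset(m, c("g1", "g2"), c("s1", "s2", "s3"),
#'                          c(0L, 0L, 1L))
#' ds
expression_dataset <- function(values, gene_ids, sample_ids, labels,
                               class_names = c("class0", "class1")) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  labels <- as.integer(labels)
  class_names <- as.character(class_names)

  if (nrow(values) != length(gene_ids))
    stop("matrix row count (", nrow(values), ") must equal number of gene ids (",
         length(gene_ids), ")")
  if (ncol(values) != length(sample_ids))
    stop("matrix column count (", ncol(values),
         ") must equal number of sample ids (", length(sample_ids), ")")
  if (length(labels) != length(sample_ids))
    stop("one label per sample required")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 5),
               collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(utils::head(unique(sample_ids[duplicated(sample_ids)]), 5),
               collapse = ", "))
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be coded 0/1")
  if (length(unique(labels)) != 2L)
    stop("exactly two classes must be present")
  if (any(tabulate(labels + 1L, 2L) < 2L))
    stop("each class needs at least 2 samples")
  if (length(class_names) != 2L)
    stop("class_names must have length 2")

  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         labels = labels, class_names = class_names),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, 2L)
  cat("<expression_dataset> ", length(x$gene_ids), " genes x ",
      length(x$sample_ids), " samples\n", sep = "")
  cat("  classes: ", x$class_names[1], " (n=", tab[1], ") vs ",
      x$class_names[2], " (n=", tab[2], ")\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

# Restrict a dataset to a subset of genes, in the given order.
subset_genes <- function(ds, gene_ids) {
  missing <- setdiff(gene_ids, ds$gene_ids)
  if (length(missing))
    stop("unknown gene id(s): ", paste(missing, collapse = ", "))
  expression_dataset(ds$values[gene_ids, , drop = FALSE], gene_ids,
                     ds$sample_ids, ds$labels, ds$class_names)
}

# TRUE when two datasets carry identical ids, labels and (toleranced) values.
datasets_equal <- function(a, b, tolerance = 1e-8) {
  identical(a$gene_ids, b$gene_ids) &&
    identical(a$sample_ids, b$sample_ids) &&
    identical(a$labels, b$labels) &&
    identical(a$class_names, b$class_names) &&
    isTRUE(all.equal(a$values, b$values, tolerance = tolerance,
                     check.attributes = FALSE))
}
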