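#' Read a curated CSV expression dataset
#'
#' Curated machine-learning-style exports store samples as rows and genes as
#' columns, with the class label in the last column (or in a named column).
#' The matrix is transposed on read so that genes are rows in memory.
#'
#' @param path Path to a CSV file with a header row.
#' @param label_column Optional name of the label column; defaults to the
#'   last column.
#'
#' @return An [expression_dataset]. Label values are mapped to `{0, 1}` in
#'   order of first appearance; the original values are kept as
#'   `class_names`.
#' @export
read_csv_dataset <- function(path, label_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) < 2L) stop("need at least 2 data rows")
  if (is.null(label_column)) label_column <- names(df)[ncol(df)]
  if (!label_column %in% names(df))
    stop("label column '", label_column, "' not found")

  raw_labels <- as.character(df[[label_column]])
  lev <- unique(raw_labels)
  if (length(lev) != 2L)
    stop("label column must contain exactly 2 distinct values, found ",
         length(lev), " (", paste(utils::head(lev, 4), collapse = ", "), ")")
  labels <- match(raw_labels, lev) - 1L

  expr <- df[setdiff(names(df), label_column)]
  for (j in seq_along(expr)) {
    v <- expr[[j]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop("non-numeric expression value at row ", bad[1],
             ", column '", names(expr)[j], "': '", v[bad[1]], "'")
      expr[[j]] <- num
    }
  }
  values <- t(as.matrix(expr))            # genes x samples
  expression_dataset(values,
                     gene_ids = names(expr),
                     sample_ids = paste0("S", seq_len(nrow(df))),
                     labels = labels,
                     class_names = lev)
}

#' Write a dataset as a curated CSV file
#'
#' Inverse of [read_csv_dataset()]: samples as rows, genes as columns, class
#' label (the class display name) in the last column.  Values are written in
#' full double precision so a read-back reproduces the dataset.
#'
#' @param ds An [expression_dataset].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dataset_csv <- function(ds, path) {
  if (length(ds$gene_ids) == 0L)
    stop("dataset has no genes; nothing written")
  df <- as.data.frame(t(ds$values), check.names = FALSE)
  df[["class"]] <- ds$class_names[ds$labels + 1L]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a ranked gene list
#'
#' Two-column CSV (`gene_id`, `score`) ordered by descending score; ties are
#' broken by gene id.
#'
#' @param gene_ids Character vector.
#' @param scores Numeric vector aligned with `gene_ids`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_list <- function(gene_ids, scores, path) {
  stopifnot(length(gene_ids) == length(scores))
  ord <- order(-scores, gene_ids)
  utils::write.csv(data.frame(gene_id = gene_ids[ord], score = scores[ord]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Specify sample classes for a SOFT file
#'
#' GDS SOFT files carry no usable class assignment, so the two class ranges
#' must be supplied by the user (from the GEO dataset description).  Ranges
#' are 1-based inclusive intervals over the sample columns in table order
#' (i.e. excluding the `ID_REF` and `IDENTIFIER` columns), written either as
#' strings like `"1-35"` / `"1-10;21-30"` or as integer vectors.
#'
#' @param class1,class2 Sample ranges for the two classes.
#' @param names Display names for the classes.
#' @return A `soft_class_spec` object.
#' @export
#' @examples
#' soft_class_spec("1-24", "25-42", names = c("control", "disease"))
soft_class_spec <- function(class1, class2, names = c("class1", "class2")) {
  c1 <- parse_sample_range(class1)
  c2 <- parse_sample_range(class2)
  if (!length(c1) || !length(c2)) stop("both classes must be non-empty")
  if (length(intersect(c1, c2)))
    stop("class ranges overlap at sample column(s): ",
         paste(utils::head(intersect(c1, c2), 5), collapse = ", "))
  if (length(names) != 2L) stop("exactly two class names required")
  structure(list(class1 = c1, class2 = c2, names = as.character(names)),
            class = "soft_class_spec")
}

# "1-35;40-42" or c(1:35, 40:42) -> sorted-in-given-order integer vector
parse_sample_range <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  out <- integer(0)
  for (part in unlist(strsplit(as.character(x), "[;,]"))) {
    part <- trimws(part)
    if (!nzchar(part)) next
    if (grepl("^\\d+-\\d+$", part)) {
      ab <- as.integer(strsplit(part, "-")[[1]])
      if (ab[1] > ab[2]) stop("empty interval: ", part)
      out <- c(out, ab[1]:ab[2])
    } else if (grepl("^\\d+$", part)) {
      out <- c(out, as.integer(part))
    } else stop("cannot parse sample range: '", part, "'")
  }
  out
}

#' Read a GEO SOFT (GDS) dataset
#'
#' Parses the `!dataset_table_begin` ... `!dataset_table_end` block of a
#' full-SOFT GDS file.  Genes are the table rows keyed by `ID_REF`; the
#' samples kept are exactly the columns selected by the class specification,
#' in specification order (class 1 columns first).
#'
#' Duplicate `ID_REF` values are made unique with a `#k` suffix.  Cells that
#' do not parse as numbers (`null`, empty, text) are handled per
#' `na_policy`: `"drop"` removes the gene row, `"impute"` replaces the cell
#' with the gene's mean over the remaining selected samples (genes with no
#' parseable value at all are always dropped).  Every such action is
#' recorded in the parse log attached as attribute `"parse_log"`.
#'
#' @param path Path to a SOFT text file.
#' @param classes A [soft_class_spec].
#' @param na_policy `"drop"` (default) or `"impute"`.
#' @return An [expression_dataset] with attribute `parse_log` (character
#'   vector of `DROPPED`/`IMPUTED`/`RENAMED` lines).
#' @export
read_soft_gds <- function(path, classes, na_policy = c("drop", "impute")) {
  na_policy <- match.arg(na_policy)
  if (!inherits(classes, "soft_class_spec"))
    stop("'classes' must be a soft_class_spec")
  if (!file.exists(path)) stop("file not found: ", path)

  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!dataset_table_begin", lines)
  end <- grep("^!dataset_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("no complete !dataset_table_begin/!dataset_table_end block found")

  header <- strsplit(lines[beg + 1L], "\t", fixed = TRUE)[[1]]
  if (length(header) < 3L || header[1] != "ID_REF" || header[2] != "IDENTIFIER")
    stop("table header must start with ID_REF, IDENTIFIER followed by sample columns")
  sample_cols <- header[-(1:2)]

  sel <- c(classes$class1, classes$class2)
  if (max(sel) > length(sample_cols))
    stop("class range refers to sample column ", max(sel), " but the table has only ",
         length(sample_cols), " sample columns")
  labels <- c(rep(0L, length(classes$class1)), rep(1L, length(classes$class2)))

  body <- lines[(beg + 2L):(end - 1L)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)

  log <- character(0)
  if (anyDuplicated(ids)) {
    dup <- which(duplicated(ids))
    new_ids <- make.unique(ids, sep = "#")
    log <- c(log, paste("RENAMED", ids[dup], "->", new_ids[dup]))
    ids <- new_ids
  }

  raw <- vapply(parts, function(p) p[2L + sel], character(length(sel)))
  raw <- matrix(raw, nrow = length(sel))   # selected samples x genes
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  vals[raw %in% c("null", "NULL", "NA", "")] <- NA_real_

  bad <- colSums(is.na(vals)) > 0L
  if (na_policy == "drop") {
    if (any(bad)) log <- c(log, paste("DROPPED", ids[bad], "unparseable value"))
    keep <- !bad
  } else {
    all_bad <- colSums(is.na(vals)) == nrow(vals)
    for (j in which(bad & !all_bad)) {
      m <- mean(vals[, j], na.rm = TRUE)
      vals[is.na(vals[, j]), j] <- m
      log <- c(log, paste("IMPUTED", ids[j], "gene-mean"))
    }
    if (any(all_bad)) log <- c(log, paste("DROPPED", ids[all_bad], "no parseable value"))
    keep <- !all_bad
  }
  if (!any(keep)) stop("no gene rows survived parsing")

  ds <- expression_dataset(t(vals[, keep, drop = FALSE]),
                           gene_ids = ids[keep],
                           sample_ids = sample_cols[sel],
                           labels = labels,
                           class_names = classes$names)
  attr(ds, "parse_log") <- log
  ds
}
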