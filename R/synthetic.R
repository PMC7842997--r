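#' Specification of a synthetic two-class expression dataset
#'
#' The generator emulates a curated two-class microarray intensity matrix:
#' log-normal positive background values identical in distribution across
#' classes, a small set of planted informative genes whose class-1 values
#' are shifted upward on the log scale by a standardised effect size, and
#' optionally a fraction of redundant genes that are jittered copies of
#' existing genes.  Defaults describe the standard recovery scenario used
#' throughout the package: 1000 genes, 5 informative at effect size 3,
#' 30 samples per class.
#'
#' @param n_genes Total genes (default 1000).
#' @param n_samples_per_class Samples per class (default 30).
#' @param n_informative Planted differential genes (default 5).
#' @param effect_size Standardised mean difference on the log scale for
#'   informative genes (default 3).
#' @param base_mean,base_sd Background intensity location and spread
#'   (defaults 100 and 20); values are drawn log-normal with
#'   `meanlog = log(base_mean)` and `sdlog = base_sd / base_mean`.
#' @param redundant_fraction Share of genes generated as noisy copies of
#'   other genes (default 0, must be < 1).
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 1000L, n_samples_per_class = 30L,
                           n_informative = 5L, effect_size = 3,
                           base_mean = 100, base_sd = 20,
                           redundant_fraction = 0, seed = 1L) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (n_samples_per_class < 2) stop("need at least 2 samples per class")
  if (n_informative > n_genes) stop("n_informative cannot exceed n_genes")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (redundant_fraction < 0 || redundant_fraction >= 1)
    stop("redundant_fraction must be in [0, 1)")
  if (base_mean <= 0 || base_sd <= 0) stop("base_mean and base_sd must be > 0")
  structure(list(n_genes = as.integer(n_genes),
                 n_samples_per_class = as.integer(n_samples_per_class),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, base_mean = base_mean,
                 base_sd = base_sd, redundant_fraction = redundant_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic two-class dataset with known ground truth
#'
#' @param spec A [synthetic_spec].
#' @return A list with `dataset` (an [expression_dataset]) and
#'   `informative` (character vector of the planted gene ids).
#' @export
make_dataset <- function(spec) {
  n <- 2L * spec$n_samples_per_class
  labels <- rep(c(0L, 1L), each = spec$n_samples_per_class)
  meanlog <- log(spec$base_mean)
  sdlog <- spec$base_sd / spec$base_mean

  n_redundant <- floor(spec$n_genes * spec$redundant_fraction)
  n_base <- spec$n_genes - n_redundant
  if (spec$n_informative > n_base)
    stop("too few non-redundant genes to hold all informative genes")

  gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
  withr::with_seed(spec$seed, {
    values <- matrix(stats::rlnorm(n_base * n, meanlog, sdlog), n_base, n)
    informative <- sort(sample.int(n_base, spec$n_informative))
    if (length(informative))
      values[informative, labels == 1L] <-
        values[informative, labels == 1L] * exp(spec$effect_size * sdlog)
    if (n_redundant > 0L) {
      src <- sample.int(n_base, n_redundant, replace = TRUE)
      jitter <- matrix(stats::rlnorm(n_redundant * n, 0, sdlog / 4),
                       n_redundant, n)
      values <- rbind(values, values[src, , drop = FALSE] * jitter)
    }
  })
  ds <- expression_dataset(values, gene_ids,
                           paste0("S", seq_len(n)), labels,
                           class_names = c("control", "case"))
  list(dataset = ds, informative = gene_ids[informative])
}

#' Serialise a synthetic dataset as a miniature GDS SOFT file
#'
#' Writes a minimal valid full-SOFT block (`!dataset_table_begin`,
#' `ID_REF` / `IDENTIFIER` / GSM columns, `!dataset_table_end`) for a
#' [make_dataset()] draw, optionally replacing expression cells with the
#' literal `null` at a given rate — useful for exercising the SOFT parser's
#' missing-value policies.  A sidecar TSV (`<path>.truth.tsv`) records the
#' planted informative genes.
#'
#' @param spec A [synthetic_spec]; must request at least one gene.
#' @param path Output path for the SOFT file.
#' @param null_rate Per-cell probability of writing `null` (default 0).
#' @return Invisibly, a list with `dataset`, `informative`, `class_spec`
#'   (the matching [soft_class_spec]) and `path`.
#' @export
make_soft_fixture <- function(spec, path, null_rate = 0) {
  if (spec$n_genes < 1L) stop("at least one gene required")
  if (null_rate < 0 || null_rate > 1) stop("null_rate must be in [0, 1]")
  gen <- make_dataset(spec)
  ds <- gen$dataset
  n <- length(ds$sample_ids)

  cells <- matrix(format(ds$values, digits = 10, trim = TRUE),
                  nrow = nrow(ds$values))
  if (null_rate > 0) {
    null_mask <- withr::with_seed(spec$seed + 1L,
      matrix(stats::runif(length(cells)) < null_rate, nrow = nrow(cells)))
    cells[null_mask] <- "null"
  }
  gsm <- sprintf("GSM%05d", seq_len(n))
  lines <- c(
    "^DATASET = synthetic",
    "!dataset_title = synthetic two-class fixture",
    paste0("!dataset_sample_count = ", n),
    "!dataset_table_begin",
    paste(c("ID_REF", "IDENTIFIER", gsm), collapse = "\t"),
    vapply(seq_len(nrow(cells)), function(i)
      paste(c(ds$gene_ids[i], ds$gene_ids[i], cells[i, ]), collapse = "\t"),
      character(1)),
    "!dataset_table_end")
  writeLines(lines, path)

  truth <- data.frame(gene_id = gen$informative, informative = 1L)
  utils::write.table(truth, paste0(path, ".truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  nc <- spec$n_samples_per_class
  cs <- soft_class_spec(sprintf("1-%d", nc), sprintf("%d-%d", nc + 1L, n),
                        names = ds$class_names)
  invisible(list(dataset = ds, informative = gen$informative,
                 class_spec = cs, path = path))
}
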