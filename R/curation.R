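#' Curation configuration
#'
#' Parameters of the near-unity-ratio gene removal rule.  A gene is judged
#' by the ratio of its two class-wise statistics (mean for stable genes,
#' median for dispersed ones); ratios inside the band `[band_low,
#' band_high]` mark a gene as carrying no between-class difference.
#'
#' @param dispersion_threshold Coefficient-of-variation cutoff above which
#'   the median criterion is used instead of the mean (default 0.15, i.e.
#'   a 15 percent coefficient of variation).
#' @param band_low Lower band edge (default 0.95).  The upper edge is its
#'   reciprocal, keeping the band symmetric under ratio inversion.
#' @return A `curation_config` list.
#' @export
curation_config <- function(dispersion_threshold = 0.15, band_low = 0.95) {
  if (dispersion_threshold < 0) stop("dispersion_threshold must be >= 0")
  if (band_low <= 0 || band_low >= 1) stop("band_low must be in (0, 1)")
  structure(list(dispersion_threshold = dispersion_threshold,
                 band_low = band_low, band_high = 1 / band_low),
            class = "curation_config")
}

#' Coefficient of variation of a gene's expression
#'
#' Dispersion is measured unit-free as `sd(x) / |mean(x)|`.  A constant
#' vector has dispersion 0; a zero-mean vector with spread has infinite
#' dispersion.
#'
#' @param values Numeric vector of length >= 2.
#' @return A non-negative fraction (possibly `Inf`).
#' @export
#' @examples
#' gene_dispersion(c(8, 10, 12))   # sd 2, mean 10 -> 0.2
gene_dispersion <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  s <- stats::sd(values)
  m <- mean(values)
  if (s == 0) return(0)
  if (m == 0) return(Inf)
  s / abs(m)
}

#' Between-class ratio of a summary statistic
#'
#' Ratio of the chosen statistic (mean or median) of class 1 over class 2.
#' Sign conventions: when both statistics are negative the ratio of absolute
#' values is returned; opposite signs yield a negative ratio (always outside
#' the removal band, so such clearly differential genes are kept); a zero
#' denominator with non-zero numerator yields `Inf`; both zero yields 1.
#'
#' @param class1_values,class2_values Non-empty numeric vectors.
#' @param criterion `"mean"` or `"median"`.
#' @return A ratio.
#' @export
curation_ratio <- function(class1_values, class2_values,
                           criterion = c("mean", "median")) {
  criterion <- match.arg(criterion)
  if (!length(class1_values) || !length(class2_values))
    stop("both classes must be non-empty")
  f <- if (criterion == "mean") mean else stats::median
  s1 <- f(class1_values)
  s2 <- f(class2_values)
  if (s1 == 0 && s2 == 0) return(1)
  if (s2 == 0) return(Inf)
  if (s1 < 0 && s2 < 0) return(abs(s1) / abs(s2))
  s1 / s2
}

#' Curate a dataset by removing near-unity-ratio genes
#'
#' For every gene the dispersion (coefficient of variation over all samples)
#' picks the criterion — median when dispersion is at or above the
#' threshold, mean otherwise — and the gene is removed when the class-wise
#' ratio of that statistic falls inside the band `[band_low, band_high]`
#' (inclusive).  Gene order is preserved among kept genes.
#'
#' @param ds An [expression_dataset].
#' @param cfg A [curation_config].
#' @return A list with `dataset` (the reduced [expression_dataset]) and
#'   `report` (a `curation_report` data frame: `gene_id`, `criterion`,
#'   `dispersion`, `ratio`, `verdict`, with attributes `n_before` /
#'   `n_after`).
#' @export
curate <- function(ds, cfg = curation_config()) {
  x1 <- ds$values[, ds$labels == 0L, drop = FALSE]
  x2 <- ds$values[, ds$labels == 1L, drop = FALSE]
  g <- length(ds$gene_ids)

  dispersion <- vapply(seq_len(g), function(i) gene_dispersion(ds$values[i, ]),
                       numeric(1))
  criterion <- ifelse(dispersion >= cfg$dispersion_threshold, "median", "mean")
  ratio <- vapply(seq_len(g), function(i)
    curation_ratio(x1[i, ], x2[i, ], criterion[i]), numeric(1))
  remove <- ratio >= cfg$band_low & ratio <= cfg$band_high

  report <- data.frame(gene_id = ds$gene_ids, criterion = criterion,
                       dispersion = dispersion, ratio = ratio,
                       verdict = ifelse(remove, "remove", "keep"),
                       stringsAsFactors = FALSE)
  attr(report, "n_before") <- g
  attr(report, "n_after") <- sum(!remove)
  class(report) <- c("curation_report", "data.frame")

  if (all(remove))
    stop("curation removed every gene; widen the band (lower band_low) ",
         "or adjust the dispersion threshold")
  kept <- ds$gene_ids[!remove]
  list(dataset = subset_genes(ds, kept), report = report)
}

#' Write a curation report as TSV
#'
#' @param report A `curation_report` from [curate()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_curation_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
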