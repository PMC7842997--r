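#' Pipeline configuration
#'
#' Bundles every stage's settings for a full run: input location and
#' format, curation, filter choice and size, wrapper and SVM settings, the
#' output directory, and one master seed from which all stage seeds are
#' derived deterministically.
#'
#' @param input Path to the input dataset.
#' @param format `"csv"` or `"soft"`.
#' @param classes A [soft_class_spec] (required for SOFT input).
#' @param curate Logical; run the curation stage?  Defaults to `TRUE` for
#'   SOFT input and `FALSE` for CSV.  Curation is obligatory for SOFT
#'   input unless `force_no_curation = TRUE`.
#' @param force_no_curation Explicit override of the SOFT curation rule.
#' @param curation A [curation_config].
#' @param filter One of `"tt"`, `"wrs"`, `"ttwrs"`, `"all"` (`"all"` runs
#'   the three branches side by side).
#' @param n_filtered Genes kept by the filter stage (default 200).
#' @param gbpso A [gbpso_config]; its seed and the SVM `cv_seed` are
#'   overwritten by seeds derived from `seed`.
#' @param outdir Output directory for run artifacts.
#' @param seed Master seed (default 1).
#' @param eval_repeats CV repetitions in the final evaluation (default 1).
#' @param n_heatmap Genes exported to the heatmap matrix (default 7; capped
#'   at the selected-subset size).
#' @return A `pipeline_config` list (not yet validated; see
#'   [validate_config()]).
#' @export
pipeline_config <- function(input, format = c("csv", "soft"), classes = NULL,
                            curate = NULL, force_no_curation = FALSE,
                            curation = curation_config(),
                            filter = c("tt", "wrs", "ttwrs", "all"),
                            n_filtered = 200L, gbpso = gbpso_config(),
                            outdir = "hidimsel_run", seed = 1L,
                            eval_repeats = 1L, n_heatmap = 7L) {
  format <- match.arg(format)
  filter <- match.arg(filter)
  structure(list(input = input, format = format, classes = classes,
                 curate = curate %||% (format == "soft"),
                 force_no_curation = force_no_curation,
                 curation = curation, filter = filter,
                 n_filtered = as.integer(n_filtered), gbpso = gbpso,
                 outdir = outdir, seed = as.integer(seed),
                 eval_repeats = as.integer(eval_repeats),
                 n_heatmap = as.integer(n_heatmap)),
            class = "pipeline_config")
}

#' Validate and normalise a pipeline configuration
#'
#' Collects every violation (not just the first) and either raises a single
#' error listing them all or returns the normalised configuration.
#'
#' @param cfg A [pipeline_config].
#' @return The normalised `pipeline_config`, or an error listing all
#'   violations.
#' @export
validate_config <- function(cfg) {
  problems <- character(0)
  if (!inherits(cfg, "pipeline_config"))
    stop("not a pipeline_config")
  if (!is.character(cfg$input) || !nzchar(cfg$input))
    problems <- c(problems, "input path is missing")
  if (cfg$format == "soft" && !inherits(cfg$classes, "soft_class_spec"))
    problems <- c(problems, "SOFT input requires a soft_class_spec ('classes')")
  if (cfg$format == "soft" && !cfg$curate && !cfg$force_no_curation)
    problems <- c(problems,
                  paste("gene reduction (curation) is obligatory for SOFT",
                        "input; set force_no_curation = TRUE to override"))
  if (cfg$n_filtered < 1L)
    problems <- c(problems, "n_filtered must be >= 1")
  if (cfg$eval_repeats < 1L)
    problems <- c(problems, "eval_repeats must be >= 1")
  if (cfg$n_heatmap < 1L)
    problems <- c(problems, "n_heatmap must be >= 1")
  if (!inherits(cfg$gbpso, "gbpso_config"))
    problems <- c(problems, "gbpso must be a gbpso_config")
  if (!inherits(cfg$curation, "curation_config"))
    problems <- c(problems, "curation must be a curation_config")
  if (length(problems))
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  cfg
}

#' Run the full selection-and-classification pipeline
#'
#' Executes read -> (curate) -> k-fold filter ranking -> top-n restriction
#' -> GBPSO-SVM wrapper -> evaluation for each requested filter branch, and
#' writes all artifacts into `cfg$outdir`: the curated dataset and curation
#' report, per-branch score tables, filtered datasets, selected-gene lists,
#' fitness traces, evaluation reports, a heatmap matrix of the final
#' subset, a plain-text log and a YAML manifest (configuration, derived
#' seeds, per-stage gene counts).  A failed stage leaves partial outputs
#' plus a `FAILED` marker naming the stage.
#'
#' @param cfg A [pipeline_config]; validated with [validate_config()].
#' @return Invisibly, a list with `outdir`, `manifest`, and per-branch
#'   `results` (each holding `score_table`, `filtered`, `selection`,
#'   `evaluation`).
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$outdir, "log.txt")
  cat("", file = log_path)
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  stage <- "setup"
  on.exit({
    if (!is.null(stage))
      writeLines(paste("FAILED at stage:", stage),
                 file.path(cfg$outdir, "FAILED"))
  })

  seeds <- derive_seeds(cfg$seed, 5,
                        c("fold_tt", "fold_wrs", "swarm", "cv", "eval"))
  counts <- list()

  stage <- "read"
  say("reading ", cfg$format, " input: ", cfg$input)
  ds <- if (cfg$format == "csv") read_csv_dataset(cfg$input)
        else read_soft_gds(cfg$input, cfg$classes)
  counts$input <- length(ds$gene_ids)
  say("loaded ", counts$input, " genes x ", length(ds$sample_ids), " samples")

  if (cfg$curate) {
    stage <- "curation"
    cur <- curate(ds, cfg$curation)
    ds <- cur$dataset
    write_curation_report(cur$report, file.path(cfg$outdir, "curation_report.tsv"))
    write_dataset_csv(ds, file.path(cfg$outdir, "curated.csv"))
    say("curation kept ", length(ds$gene_ids), " of ", counts$input, " genes")
  }
  counts$curated <- length(ds$gene_ids)

  branches <- if (cfg$filter == "all") c("tt", "wrs", "ttwrs") else cfg$filter
  need <- unique(unlist(lapply(branches, function(b)
    if (b == "ttwrs") c("tt", "wrs") else b)))

  stage <- "filtration"
  base_tables <- list()
  for (f in need) {
    say("ranking genes with ", f, " filter (10-fold)")
    base_tables[[f]] <- kfold_filter_weights(ds, f, k = 10,
                                             seed = seeds[[paste0("fold_", f)]])
  }

  results <- list()
  for (b in branches) {
    tab <- if (b == "ttwrs") combine_tt_wrs(base_tables$tt, base_tables$wrs)
           else base_tables[[b]]
    write_score_table(tab, file.path(cfg$outdir, paste0("scores_", b, ".tsv")))
    filtered <- select_top(tab, ds, cfg$n_filtered)
    counts[[paste0("filtered_", b)]] <- length(filtered$gene_ids)
    write_dataset_csv(filtered, file.path(cfg$outdir, paste0("filtered_", b, ".csv")))

    stage <- paste0("gbpso_", b)
    gcfg <- cfg$gbpso
    gcfg$seed <- seeds[["swarm"]]
    gcfg$svm$cv_seed <- seeds[["cv"]]
    say("running GBPSO-SVM on ", b, " branch (", length(filtered$gene_ids),
        " genes, population ", gcfg$population, ", ", gcfg$iterations,
        " iterations)")
    sel <- run_gbpso(filtered, gcfg)
    counts[[paste0("selected_", b)]] <- length(sel$selected_gene_ids)
    say(b, ": ", length(sel$selected_gene_ids), " genes selected, CV fitness ",
        sprintf("%.4f", sel$best_fitness))
    mask_weights <- tab$weight[match(filtered$gene_ids, tab$gene_id)]
    write_gene_list(sel$selected_gene_ids,
                    mask_weights[sel$best_mask == 1L],
                    file.path(cfg$outdir, paste0("selected_genes_", b, ".csv")))
    write_fitness_trace(sel, file.path(cfg$outdir, paste0("trace_", b, ".tsv")))

    stage <- paste0("evaluation_", b)
    rep <- evaluate_subset(filtered, sel$best_mask, gcfg$svm,
                           repeats = cfg$eval_repeats, seed = seeds[["eval"]])
    write_evaluation_report(rep, file.path(cfg$outdir,
                                           paste0("evaluation_", b, ".tsv")))
    say(b, sprintf(": accuracy %.1f%% ± %.1f, precision %s", rep$accuracy,
                   rep$accuracy_sd,
                   ifelse(is.na(rep$precision), "n/a",
                          sprintf("%.1f%%", rep$precision))))
    results[[b]] <- list(score_table = tab, filtered = filtered,
                         selection = sel, evaluation = rep)
  }

  stage <- "heatmap"
  final <- results[[branches[length(branches)]]]
  hm_genes <- utils::head(final$selection$selected_gene_ids, cfg$n_heatmap)
  if (length(hm_genes))
    heatmap_matrix(final$filtered, hm_genes,
                   path = file.path(cfg$outdir, "heatmap_matrix.tsv"))

  stage <- "manifest"
  manifest <- list(
    input = cfg$input, format = cfg$format, curate = cfg$curate,
    filter = cfg$filter, n_filtered = cfg$n_filtered,
    master_seed = cfg$seed, derived_seeds = as.list(seeds),
    gbpso = list(population = cfg$gbpso$population,
                 iterations = cfg$gbpso$iterations,
                 svm_degree = cfg$gbpso$svm$degree,
                 svm_cost = cfg$gbpso$svm$cost,
                 cv_folds = cfg$gbpso$svm$cv_folds),
    gene_counts = counts)
  yaml::write_yaml(manifest, file.path(cfg$outdir, "manifest.yaml"))
  say("done; artifacts in ", cfg$outdir)

  stage <- NULL   # disarm the failure marker
  invisible(list(outdir = cfg$outdir, manifest = manifest, results = results))
}
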