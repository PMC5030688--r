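# End-to-end orchestration: downsample -> RPKM+TC -> tracer profiling ->
# prevalence filter -> log-ratio normalization -> cross-correlation ->
# best hits -> (optional) truth scoring. One function, one seed, one
# deterministic report.

#' Run the full OTU-MGS linking pipeline
#'
#' Executes the fixed stage order on in-memory inputs: per-sample
#' downsampling of gene counts (skipped when `target_depth` is `NULL`),
#' RPKM+TC normalization, within-MGS connectivity + tracer selection + mean
#' tracer profiles, prevalence filtering of both the MGS and OTU tables,
#' log-ratio normalization of both, cross-table Pearson correlation, and
#' best/second-best hit calling against the cutoff. Samples must agree
#' between the gene and OTU tables before any computation starts; samples
#' that end up all-zero in either filtered table are dropped from both
#' before log normalization. Identical inputs, parameters and seed
#' reproduce an identical report.
#'
#' @param gene_counts Gene count matrix (genes x samples).
#' @param gene_lengths Gene length table (see [gene_length_table()]).
#' @param membership MGS membership table (`gene_id`, `mgs_id`).
#' @param otu_counts OTU count matrix (OTUs x samples).
#' @param target_depth Downsampling depth for gene counts; `NULL` skips
#'   downsampling.
#' @param seed Integer seed for the downsampling draw.
#' @param on_shallow Handling of samples below `target_depth`
#'   (see [downsample_counts()]); under `"drop"` the dropped samples are
#'   removed from both tables.
#' @param k_tracers Tracer genes per MGS (default 50).
#' @param rho_threshold Spearman edge threshold for connectivity
#'   (default 0.7).
#' @param pseudocount Ratio-scale pseudocount for the log transform
#'   (default 1e-17).
#' @param min_prevalence Exclusive minimum number of positive samples
#'   (default 10).
#' @param cutoff Pearson cutoff for a passing link (default 0.65).
#' @param direction `"otu"`: each OTU queries the MGS candidates (the
#'   "most wanted" design); `"mgs"`: each MGS queries the OTUs (the
#'   validation design).
#' @param truth Optional `"synthetic_truth"` object or `(otu_id, mgs_id)`
#'   data.frame; when given, a recovery summary is added to the report.
#' @param out_dir Optional directory; when given, the links table, tracer
#'   lists, MGS matrix and stage log are written there as TSV. The
#'   directory must not already exist (each run gets a fresh one).
#' @return List of class `"taxalink_report"`: `links` (data.frame),
#'   `mgs_models`, `mgs_matrix`, `stages` (stage log data.frame),
#'   `dropped` (per-filter row ids), `recovery` (or `NULL`), `params`.
#' @export
run_pipeline <- function(gene_counts, gene_lengths, membership, otu_counts,
                         target_depth = NULL, seed = 1L,
                         on_shallow = c("keep", "error", "drop"),
                         k_tracers = 50, rho_threshold = 0.7,
                         pseudocount = 1e-17, min_prevalence = 10,
                         cutoff = 0.65, direction = c("otu", "mgs"),
                         truth = NULL, out_dir = NULL) {
  direction <- match.arg(direction)
  on_shallow <- match.arg(on_shallow)
  stages <- list()
  log_stage <- function(name, m) {
    stages[[length(stages) + 1]] <<- data.frame(stage = name, rows = nrow(m),
                                                samples = ncol(m))
  }

  if (!setequal(colnames(gene_counts), colnames(otu_counts))) {
    stop("gene and OTU tables disagree on sample ids", call. = FALSE)
  }
  otu_counts <- otu_counts[, colnames(gene_counts), drop = FALSE]
  log_stage("input_genes", gene_counts)
  log_stage("input_otus", otu_counts)

  if (!is.null(target_depth)) {
    gene_counts <- downsample_counts(gene_counts, target_depth, seed,
                                     on_shallow = on_shallow)
    otu_counts <- otu_counts[, colnames(gene_counts), drop = FALSE]
    log_stage("downsample", gene_counts)
  }

  abundance <- normalize_rpkm_tc(gene_counts, gene_lengths)
  log_stage("normalize_rpkm_tc", abundance)

  models <- build_mgs_models(abundance, membership, k = k_tracers,
                             rho_threshold = rho_threshold)
  mgs_matrix <- mgs_abundance(abundance, models)
  log_stage("mgs_abundance", mgs_matrix)

  mgs_f <- prevalence_filter(mgs_matrix, min_prevalence)
  otu_f <- prevalence_filter(otu_counts, min_prevalence)
  log_stage("prevalence_mgs", mgs_f$kept)
  log_stage("prevalence_otus", otu_f$kept)
  if (nrow(mgs_f$kept) == 0 || nrow(otu_f$kept) == 0) {
    stop("no entities left after prevalence filtering", call. = FALSE)
  }

  # a sample that is all-zero in either filtered table cannot be log-ratio
  # normalized; drop it from both so the sample sets stay aligned
  zero <- colSums(mgs_f$kept) == 0 | colSums(otu_f$kept) == 0
  if (any(zero)) {
    mgs_f$kept <- mgs_f$kept[, !zero, drop = FALSE]
    otu_f$kept <- otu_f$kept[, !zero, drop = FALSE]
  }
  mgs_log <- normalize_profiles(mgs_f$kept, pseudocount)
  otu_log <- normalize_profiles(otu_f$kept, pseudocount)
  log_stage("normalize_profiles", mgs_log)

  corr <- pearson_cross(otu_log, mgs_log)
  log_stage("pearson_cross", corr)
  links <- best_hits(corr, cutoff = cutoff,
                     direction = if (direction == "otu") "query_rows"
                                 else "query_cols")
  log_stage("best_hits", links)

  recovery <- if (!is.null(truth) && direction == "otu") {
    evaluate_recovery(links, truth)
  } else NULL

  report <- structure(
    list(links = links, mgs_models = models, mgs_matrix = mgs_matrix,
         stages = do.call(rbind, stages),
         dropped = list(mgs = mgs_f$dropped, otus = otu_f$dropped,
                        zero_samples = colnames(gene_counts)[zero]),
         recovery = recovery,
         params = list(target_depth = target_depth, seed = seed,
                       on_shallow = on_shallow, k_tracers = k_tracers,
                       rho_threshold = rho_threshold,
                       pseudocount = pseudocount,
                       min_prevalence = min_prevalence, cutoff = cutoff,
                       direction = direction)),
    class = "taxalink_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report to a fresh directory
#'
#' Emits `links.tsv`, `mgs_matrix.tsv`, `tracers.tsv`, `stages.tsv` and the
#' resolved parameters as `params.yaml`. Refuses to overwrite an existing
#' directory so no run mutates another run's outputs.
#'
#' @param report A `"taxalink_report"`.
#' @param out_dir Directory to create.
#' @export
write_report <- function(report, out_dir) {
  if (dir.exists(out_dir)) {
    stop("output directory already exists: ", out_dir, call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE)
  write_tsv(report$links, file.path(out_dir, "links.tsv"))
  write_count_matrix(report$mgs_matrix, file.path(out_dir, "mgs_matrix.tsv"),
                     id_col = "mgs_id")
  tracers <- do.call(rbind, lapply(report$mgs_models, function(m) {
    data.frame(mgs_id = m$mgs_id, rank = seq_along(m$tracer_genes),
               gene_id = m$tracer_genes, stringsAsFactors = FALSE)
  }))
  write_tsv(tracers, file.path(out_dir, "tracers.tsv"))
  write_tsv(report$stages, file.path(out_dir, "stages.tsv"))
  writeLines(yaml::as.yaml(report$params), file.path(out_dir, "params.yaml"))
  invisible(out_dir)
}

#' Print method for pipeline reports
#'
#' @param x A `"taxalink_report"`.
#' @param ... Unused.
#' @export
print.taxalink_report <- function(x, ...) {
  cat("taxalink pipeline report\n")
  cat(sprintf("  direction: per-%s best hit; cutoff %.3f\n",
              x$params$direction, x$params$cutoff))
  print(x$stages, row.names = FALSE)
  cat(sprintf("  passing links: %d / %d queries\n",
              sum(x$links$passes_cutoff), nrow(x$links)))
  if (!is.null(x$recovery)) {
    cat(sprintf("  recovery vs truth: precision %.3f, recall %.3f (%d true pairs)\n",
                x$recovery$precision, x$recovery$recall,
                x$recovery$n_true_pairs))
  }
  invisible(x)
}

#' Read a pipeline run configuration from YAML
#'
#' The YAML file may carry input paths (`gene_counts`, `gene_lengths`,
#' `membership`, `otu_counts`) and any of the [run_pipeline()] parameters.
#'
#' @param path Path to a YAML file.
#' @return Named list of configuration entries.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the pipeline from a configuration list or YAML file
#'
#' Resolves the four input paths through the io readers, then calls
#' [run_pipeline()] with the remaining entries as parameters. Entries given
#' in `...` override the file.
#'
#' @param config Path to a YAML file or a named list.
#' @param ... Overrides for individual configuration entries.
#' @return A `"taxalink_report"`.
#' @export
run_pipeline_files <- function(config, ...) {
  if (is.character(config)) config <- read_run_config(config)
  over <- list(...)
  config[names(over)] <- over
  inputs <- list(
    gene_counts = read_count_matrix(config$gene_counts),
    gene_lengths = read_gene_lengths(config$gene_lengths),
    membership = read_membership(config$membership),
    otu_counts = if (grepl("\\.qiime\\.|otu_table", basename(config$otu_counts))) {
      read_qiime_otu_table(config$otu_counts)$counts
    } else {
      read_count_matrix(config$otu_counts)
    })
  keep <- intersect(names(config),
                    setdiff(names(formals(run_pipeline)),
                            names(inputs)))
  do.call(run_pipeline, c(inputs, config[keep]))
}
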