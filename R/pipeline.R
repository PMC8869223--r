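# End-to-end orchestration: differential expression -> gene consensus ->
# pathway enrichment -> report tables, with a run manifest. The stage outputs
# are plain TSVs shaped like the figures of a cross-study liver-transcriptome
# consensus analysis (gene x comparison logFC heatmap, pathway x comparison
# signed -log10 p matrix, genes-of-interest validation table).

default_thresholds <- function() {
  list(logfc_min = 0.1, p_max = 0.05, min_conditions = 3L, min_studies = 2L,
       enrich_n_top = 250L, enrich_p_max = 0.05,
       pathway_p_max = 0.01, pathway_min_comparisons = 3L)
}

#' Validate a pipeline configuration
#'
#' Fails fast — before any computation — when the configuration cannot
#' support a full run: unknown mode, missing input paths in `files` mode, or
#' missing design in `synthetic` mode.
#'
#' @param config List, or path to a YAML file.
#' @return The normalized configuration list, invisibly usable by
#'   [run_pipeline()].
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$mode) || !config$mode %in% c("synthetic", "files"))
    hep_stop("config", "config$mode must be 'synthetic' or 'files'")
  if (config$mode == "files") {
    for (field in c("studies", "comparisons", "gmt")) {
      if (is.null(config[[field]]))
        hep_stop("config", "files mode: config$%s is required", field)
    }
    paths <- c(vapply(config$studies, `[[`, "", "path"),
               config$comparisons, config$gmt, config$goi)
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0L)
      hep_stop("config", "input file not found: %s", missing[1L])
  } else {
    if (is.null(config$seed)) config$seed <- 1L
  }
  th <- default_thresholds()
  th[names(config$thresholds)] <- config$thresholds
  config$thresholds <- th
  config
}

pipeline_inputs <- function(config) {
  if (config$mode == "synthetic") {
    syn <- config$synthetic
    design <- simulation_design(
      n_studies = if (is.null(syn$n_studies)) 5L else syn$n_studies,
      comparisons_per_study = if (is.null(syn$comparisons_per_study)) 2L
                              else syn$comparisons_per_study,
      n_genes = if (is.null(syn$n_genes)) 2000L else syn$n_genes,
      n_samples_per_group = if (is.null(syn$n_samples_per_group)) 8L
                            else syn$n_samples_per_group,
      planted_genes = syn$planted_genes,
      planted_pathways = syn$planted_pathways,
      seed = config$seed
    )
    cohort <- generate_expression_studies(design)
    collection <- generate_gmt(design)
    list(studies = cohort$studies, comparisons = cohort$comparisons,
         collection = collection, truth = cohort$truth, goi = NULL)
  } else {
    studies <- lapply(config$studies, function(s) {
      read_expression(s$path, study_id = s$study_id,
                      scale = if (is.null(s$scale)) "log2" else s$scale,
                      platform = if (is.null(s$platform)) "microarray"
                                 else s$platform)
    })
    names(studies) <- vapply(studies, `[[`, "", "study_id")
    comparisons <- read_comparisons(config$comparisons, studies = studies)
    collection <- read_gmt(config$gmt, universe = config$universe)
    goi <- if (!is.null(config$goi)) read_genes_of_interest(config$goi)
    list(studies = studies, comparisons = comparisons,
         collection = collection, truth = NULL, goi = goi)
  }
}

#' Run the full consensus pipeline
#'
#' Executes differential expression for every configured comparison, the
#' cross-comparison gene consensus (selection, ranking, optional
#' genes-of-interest validation), per-comparison pathway enrichment and the
#' pathway consensus, then writes all stage outputs as TSV plus a JSON run
#' manifest. Given identical configuration and seed, the TSV outputs are
#' byte-identical across runs.
#'
#' @param config Configuration list or YAML path, see [validate_config()].
#'   In `synthetic` mode the inputs are generated from a
#'   [simulation_design()]; in `files` mode they are read from disk.
#' @param out_dir Output directory.
#' @return The run manifest (list), invisibly. On disk: `de/<comparison>.tsv`,
#'   `consensus_full.tsv`, `consensus_top50_heatmap.tsv`,
#'   `genes_of_interest.tsv` (when a list is configured),
#'   `enrichment/<comparison>.tsv`, `pathway_consensus.tsv`,
#'   `pathway_heatmap.tsv`, `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  inputs <- pipeline_inputs(config)
  th <- config$thresholds
  dir.create(file.path(out_dir, "de"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "enrichment"), showWarnings = FALSE)
  paths <- character()

  results <- lapply(inputs$comparisons, function(cs) {
    study <- inputs$studies[[cs$study_id]]
    if (is.null(study))
      hep_stop("config", "comparison '%s' references unknown study '%s'",
               cs$comparison_id, cs$study_id)
    fit_comparison(study, cs)
  })
  for (r in results) {
    p <- file.path(out_dir, "de", paste0(attr(r, "comparison_id"), ".tsv"))
    write_de_result(r, p)
    paths[paste0("de_", attr(r, "comparison_id"))] <- p
  }

  records <- build_consensus(results, inputs$comparisons,
                             collection = inputs$collection,
                             logfc_min = th$logfc_min, p_max = th$p_max,
                             min_conditions = th$min_conditions,
                             min_studies = th$min_studies)
  paths["consensus_full"] <- write_tsv(rank_consensus(records),
                                       file.path(out_dir, "consensus_full.tsv"))
  top50 <- rank_consensus(records[records$consensus, , drop = FALSE],
                          annotated_only = TRUE, top_n = 50L)
  gene_hm <- make_heatmap_table(results, top50$gene)
  paths["consensus_top50_heatmap"] <-
    write_tsv(gene_hm, file.path(out_dir, "consensus_top50_heatmap.tsv"))
  if (!is.null(inputs$goi)) {
    goi_tab <- validate_genes_of_interest(inputs$goi, records,
                                          min_datasets = th$min_conditions)
    paths["genes_of_interest"] <-
      write_tsv(goi_tab, file.path(out_dir, "genes_of_interest.tsv"))
  }

  enr <- lapply(results, function(r)
    enrich_comparison(r, inputs$collection, n_top = th$enrich_n_top,
                      p_max = th$enrich_p_max))
  for (e in enr) {
    cid <- e$comparison_id[1L]
    p <- file.path(out_dir, "enrichment", paste0(cid, ".tsv"))
    write_tsv(e, p)
    paths[paste0("enrichment_", cid)] <- p
  }
  enr_all <- do.call(rbind, lapply(enr, as.data.frame))
  pw <- pathway_consensus(enr_all, p_max = th$pathway_p_max,
                          min_comparisons = th$pathway_min_comparisons)
  paths["pathway_consensus"] <-
    write_tsv(as.data.frame(pw), file.path(out_dir, "pathway_consensus.tsv"))
  pw_hm <- make_pathway_heatmap(enr_all, pw$pathway_id[pw$consensus])
  paths["pathway_heatmap"] <-
    write_tsv(pw_hm, file.path(out_dir, "pathway_heatmap.tsv"))

  counts <- vapply(paths, function(p) length(readLines(p)) - 1L, integer(1L))
  manifest <- list(
    tool = "hepmeta", version = as.character(utils::packageVersion("hepmeta")),
    mode = config$mode, seed = config$seed,
    config_hash = config_hash(config),
    thresholds = th,
    n_comparisons = length(results),
    n_genes_consensus = sum(records$consensus),
    n_genes_consensus_annotated = sum(records$consensus & records$annotated %in% TRUE),
    n_pathways_consensus = sum(pw$consensus),
    outputs = as.list(paths), row_counts = as.list(counts),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(inputs$truth) &&
      length(inputs$truth$consensus_gene_ids) > 0L) {
    truth_ids <- inputs$truth$consensus_gene_ids
    flagged <- records$gene[records$consensus]
    manifest$consensus_recall <- mean(truth_ids %in% flagged)
    manifest$consensus_precision <-
      if (length(flagged) > 0L) mean(flagged %in% truth_ids) else NA
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# stable hash of the configuration: canonical JSON -> md5
config_hash <- function(config) {
  config$timestamp <- NULL
  canon <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                            digits = NA)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(canon), tf)
  unname(tools::md5sum(tf))
}

#' Gene x comparison heatmap table of signed logFC
#'
#' One row per selected gene, one column per comparison, cells holding the
#' comparison's log2 fold change; genes unmeasured in a comparison get an
#' explicit `NA`, never zero.
#'
#' @param results List of `de_result` objects.
#' @param genes Character vector of genes to display (row order preserved).
#' @return Data frame: `gene` column plus one numeric column per comparison.
#' @export
make_heatmap_table <- function(results, genes) {
  comp_ids <- vapply(results, attr, "", "comparison_id")
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (i in seq_along(results)) {
    r <- results[[i]]
    out[[comp_ids[i]]] <- r$logfc[match(genes, r$gene)]
  }
  if (length(genes) == 0L)
    hep_warn("heatmap table is empty: no gene met the selection criteria")
  out
}

#' Pathway x comparison heatmap table of signed -log10 p
#'
#' For each selected pathway and comparison, the cell is `-log10(p)` of the
#' better-supported direction, signed positive for up- and negative for
#' down-regulation; pathways untested in a comparison get `NA`.
#'
#' @param enrichment Combined enrichment rows (see [enrich_comparison()]).
#' @param pathways Pathways to display.
#' @return Data frame: `pathway_id` column plus one column per comparison.
#' @export
make_pathway_heatmap <- function(enrichment, pathways) {
  x <- as.data.frame(enrichment)
  comp_ids <- unique(x$comparison_id)
  out <- data.frame(pathway_id = pathways, stringsAsFactors = FALSE)
  for (cid in comp_ids) {
    cells <- vapply(pathways, function(pid) {
      g <- x[x$comparison_id == cid & x$pathway_id == pid, , drop = FALSE]
      if (nrow(g) == 0L) return(NA_real_)
      best <- g[which.min(g$p), ]
      sign <- if (best$direction == "up") 1 else -1
      sign * -log10(max(best$p, .Machine$double.xmin))
    }, numeric(1L))
    out[[cid]] <- unname(cells)
  }
  if (length(pathways) == 0L)
    hep_warn("pathway heatmap is empty: no pathway met the consensus rule")
  out
}
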