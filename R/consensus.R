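# Cross-comparison consensus: which genes are consistently dysregulated in
# offspring of obese mothers across independent expression studies, how they
# rank, and how a literature-derived genes-of-interest list fares against the
# same evidence.

#' Combine p-values with Fisher's method
#'
#' `X = -2 * sum(log(p_i))` is referred to the upper tail of a chi-squared
#' distribution with `2k` degrees of freedom. For a single p-value the
#' combination is the identity.
#'
#' @param pvalues Numeric vector of p-values, all in `(0, 1]`.
#' @return The combined p-value.
#' @export
fisher_combine <- function(pvalues) {
  if (length(pvalues) == 0L)
    hep_stop("data", "fisher_combine: empty p-value list")
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    hep_stop("data", "fisher_combine: p-values must lie in (0, 1]")
  x <- -2 * sum(log(pvalues))
  stats::pchisq(x, df = 2 * length(pvalues), lower.tail = FALSE)
}

#' Build cross-comparison consensus records
#'
#' For every gene measured in at least one comparison, counts the comparisons
#' in which it qualifies as up- (logFC > `logfc_min`, p < `p_max`) or
#' down-regulated (logFC < `-logfc_min`, p < `p_max`), the distinct studies
#' among qualifying comparisons, the median absolute logFC over qualifying
#' comparisons, and Fisher's combination of the gene's p-values over all
#' comparisons where it is measured. A gene is flagged `consensus` when it
#' qualifies in at least `min_conditions` comparisons or in comparisons from
#' at least `min_studies` distinct studies.
#'
#' @param results List of `de_result` objects (one per comparison).
#' @param specs List of [comparison_spec()] objects covering the results'
#'   comparison ids (used for the study-of-comparison map).
#' @param collection Optional [gene_set_collection()]; when given, the
#'   `annotated` flag marks genes present in its universe.
#' @param logfc_min,p_max Per-comparison qualification gates.
#' @param min_conditions Minimum qualifying comparisons (first clause).
#' @param min_studies Minimum distinct studies among qualifying comparisons
#'   (second clause).
#' @return Data frame of class `consensus_table`, one row per measured gene:
#'   `gene`, `n_up`, `n_down`, `n_measured`, `n_studies_hit`,
#'   `median_abs_logfc`, `fisher_p`, `annotated`, `consensus`.
#' @export
build_consensus <- function(results, specs, collection = NULL,
                            logfc_min = 0.1, p_max = 0.05,
                            min_conditions = 3L, min_studies = 2L) {
  if (length(results) == 0L)
    hep_stop("config", "build_consensus: need at least one de_result")
  if (logfc_min <= 0 || p_max <= 0)
    hep_stop("config", "thresholds must be positive")
  comp_ids <- unname(vapply(results, attr, "", "comparison_id"))
  study_of <- vapply(specs, `[[`, "", "study_id")
  names(study_of) <- vapply(specs, `[[`, "", "comparison_id")
  if (length(setdiff(comp_ids, names(study_of))) > 0L)
    hep_stop("config", "no comparison_spec for comparison '%s'",
             setdiff(comp_ids, names(study_of))[1L])

  long <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(gene = r$gene, comparison = comp_ids[i],
               study = study_of[[comp_ids[i]]], logfc = r$logfc, p = r$p,
               stringsAsFactors = FALSE)
  }))
  genes <- sort(unique(long$gene))
  if (length(results) > 1L) {
    counts <- table(long$gene)
    if (max(counts) < 2L)
      hep_stop("processing", "no gene is measured in more than one comparison")
  }
  long$up <- long$logfc > logfc_min & long$p < p_max
  long$down <- long$logfc < -logfc_min & long$p < p_max
  long$qual <- long$up | long$down

  by_gene <- split(long, long$gene)
  rows <- lapply(by_gene, function(g) {
    q <- g[g$qual, , drop = FALSE]
    data.frame(
      gene = g$gene[1L],
      n_up = sum(g$up), n_down = sum(g$down), n_measured = nrow(g),
      n_studies_hit = length(unique(q$study)),
      median_abs_logfc = if (nrow(q) > 0L) stats::median(abs(q$logfc)) else 0,
      fisher_p = fisher_combine(g$p),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[match(genes, out$gene), , drop = FALSE]
  out$annotated <- if (!is.null(collection)) out$gene %in% collection$universe
                   else NA
  out$consensus <- (out$n_up + out$n_down) >= min_conditions |
    out$n_studies_hit >= min_studies
  attr(out, "thresholds") <- list(logfc_min = logfc_min, p_max = p_max,
                                  min_conditions = min_conditions,
                                  min_studies = min_studies)
  class(out) <- c("consensus_table", "data.frame")
  out
}

#' @export
print.consensus_table <- function(x, n = 10L, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "<consensus_table> %d genes, %d consensus (|logFC|>%g, p<%g, >=%d comparisons or >=%d studies)\n",
    nrow(x), sum(x$consensus), th$logfc_min, th$p_max, th$min_conditions,
    th$min_studies))
  print.data.frame(utils::head(rank_consensus(x), n), digits = 4)
  invisible(x)
}

#' Rank consensus records
#'
#' Descending lexicographic order on the three keys of the consensus ranking:
#' number of qualifying comparisons (`n_up + n_down`), median absolute logFC,
#' and Fisher's combined p-value (smaller is stronger). Ties beyond the three
#' keys break by gene id.
#'
#' @param records A `consensus_table` (or compatible data frame).
#' @param annotated_only Keep only genes present in the annotation universe.
#' @param top_n Optionally truncate to the first `top_n` rows after sorting.
#' @return The sorted (possibly restricted) table.
#' @export
rank_consensus <- function(records, annotated_only = FALSE, top_n = NULL) {
  x <- as.data.frame(records)
  if (annotated_only) {
    if (all(is.na(x$annotated)))
      hep_stop("config", "no annotation available: build consensus with a collection")
    x <- x[!is.na(x$annotated) & x$annotated, , drop = FALSE]
  }
  ord <- order(-(x$n_up + x$n_down), -x$median_abs_logfc, x$fisher_p, x$gene,
               method = "radix")
  x <- x[ord, , drop = FALSE]
  if (!is.null(top_n)) x <- utils::head(x, top_n)
  rownames(x) <- NULL
  x
}

#' Validate a genes-of-interest list against the consensus evidence
#'
#' For every listed gene, reports the up/down qualification counts, median
#' absolute logFC and Fisher combined p from the consensus records, and a
#' `validated` flag for genes qualifying in at least `min_datasets`
#' comparisons. Genes never measured in any comparison get status `absent`
#' (counts `NA`), not zero.
#'
#' @param goi Data frame with a `gene` column (see
#'   [read_genes_of_interest()]).
#' @param records A `consensus_table`.
#' @param min_datasets Minimum qualifying comparisons for validation.
#' @return Data frame with one row per listed gene: `gene`, `status`
#'   (`"measured"`/`"absent"`), `n_up`, `n_down`, `median_abs_logfc`,
#'   `fisher_p`, `validated`.
#' @export
validate_genes_of_interest <- function(goi, records, min_datasets = 3L) {
  if (is.null(goi) || nrow(goi) == 0L)
    hep_stop("config", "genes-of-interest list is empty")
  idx <- match(goi$gene, records$gene)
  found <- !is.na(idx)
  out <- data.frame(
    gene = goi$gene, status = ifelse(found, "measured", "absent"),
    n_up = NA_integer_, n_down = NA_integer_,
    median_abs_logfc = NA_real_, fisher_p = NA_real_,
    validated = NA, stringsAsFactors = FALSE
  )
  out$n_up[found] <- records$n_up[idx[found]]
  out$n_down[found] <- records$n_down[idx[found]]
  out$median_abs_logfc[found] <- records$median_abs_logfc[idx[found]]
  out$fisher_p[found] <- records$fisher_p[idx[found]]
  out$validated[found] <- (out$n_up[found] + out$n_down[found]) >= min_datasets
  out
}
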