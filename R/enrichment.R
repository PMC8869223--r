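# Per-comparison over-representation analysis: top-250 up- and down-regulated
# annotated genes, a hypergeometric test per (pathway, direction), and the
# cross-comparison pathway-consensus rule (p < 0.01 in >= 3 comparisons).

#' Upper-tail hypergeometric over-representation p-value
#'
#' Probability of observing at least `k` pathway members in a selection of
#' size `n` drawn without replacement from a universe of `N` genes of which
#' `K` belong to the pathway; upper tail inclusive of the observed `k`.
#'
#' @param k Overlap between selection and pathway.
#' @param n Selection size.
#' @param K Pathway size within the universe.
#' @param N Universe size.
#' @return The p-value, in `(0, 1]`.
#' @export
hypergeom_test <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || n > N || K > N || k > min(n, K))
    hep_stop("data",
             "inconsistent hypergeometric counts: k=%d n=%d K=%d N=%d",
             k, n, K, N)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Select the most up- and down-regulated annotated genes of one comparison
#'
#' Genes with a p-value above `p_max` are excluded; the remainder are ranked
#' by signed log2 fold change, and up to `n_top` genes with positive logFC
#' (descending) form the up set, up to `n_top` with negative logFC
#' (ascending) the down set. When fewer than `n_top` qualify in a direction,
#' all qualifying genes are returned. Ties at the cut break by gene id. The
#' two sets are disjoint by construction.
#'
#' @param result A `de_result`, already restricted to the enrichment universe
#'   by [enrich_comparison()] (or by the caller).
#' @param n_top Genes per direction.
#' @param p_max Significance gate.
#' @return List with character vectors `up` and `down`.
#' @export
select_top_dysregulated <- function(result, n_top = 250L, p_max = 0.05) {
  ok <- result$p <= p_max
  up <- result[ok & result$logfc > 0, c("gene", "logfc")]
  down <- result[ok & result$logfc < 0, c("gene", "logfc")]
  up <- up[order(-up$logfc, up$gene, method = "radix"), ]
  down <- down[order(down$logfc, down$gene, method = "radix"), ]
  list(up = utils::head(up$gene, n_top), down = utils::head(down$gene, n_top))
}

#' Hypergeometric enrichment of every pathway in one comparison
#'
#' The universe is the set of annotated genes measured in this comparison
#' (intersection of the collection's universe with the result's genes); the
#' up and down selections come from [select_top_dysregulated()] applied to
#' the annotated part of the result; each pathway is tested independently in
#' both directions.
#'
#' @param result A `de_result`.
#' @param collection A [gene_set_collection()].
#' @param n_top,p_max Selection parameters, see [select_top_dysregulated()].
#' @return Data frame of class `enrichment_table`: one row per
#'   (pathway, direction) with columns `comparison_id`, `pathway_id`,
#'   `direction`, `k`, `n`, `K`, `N`, `p`.
#' @export
enrich_comparison <- function(result, collection, n_top = 250L, p_max = 0.05) {
  if (!inherits(collection, "gene_set_collection"))
    hep_stop("config", "collection must be a gene_set_collection")
  comp_id <- attr(result, "comparison_id")
  universe <- intersect(collection$universe, result$gene)
  N <- length(universe)
  if (N == 0L)
    hep_stop("processing", "comparison '%s': no annotated gene measured", comp_id)
  annotated <- result[result$gene %in% universe, , drop = FALSE]
  sel <- select_top_dysregulated(annotated, n_top = n_top, p_max = p_max)
  if (length(sel$up) == 0L && length(sel$down) == 0L)
    hep_warn("comparison '%s': empty up and down selections", comp_id)
  rows <- lapply(names(collection$sets), function(pid) {
    members <- intersect(collection$sets[[pid]], universe)
    K <- length(members)
    do.call(rbind, lapply(c("up", "down"), function(dir) {
      s <- sel[[dir]]
      k <- length(intersect(s, members))
      p <- if (K == 0L || length(s) == 0L) 1
           else hypergeom_test(k, length(s), K, N)
      data.frame(comparison_id = comp_id, pathway_id = pid, direction = dir,
                 k = k, n = length(s), K = K, N = N, p = p,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Cross-comparison pathway consensus
#'
#' Per pathway and comparison, a direction call is made when the up- or
#' down-direction enrichment reaches `p < p_max` (the smaller p wins when
#' both do). Pathways called in at least `min_comparisons` comparisons are
#' flagged as consensus-dysregulated.
#'
#' @param results One `enrichment_table` (or several rbind-ed), covering at
#'   least `min_comparisons` distinct comparisons.
#' @param p_max Per-comparison significance threshold.
#' @param min_comparisons Replication requirement.
#' @return Data frame of class `pathway_consensus`: `pathway_id`,
#'   `n_comparisons_hit`, `n_up`, `n_down`, `consensus`, plus attribute
#'   `calls` holding the per-(pathway, comparison) direction calls.
#' @export
pathway_consensus <- function(results, p_max = 0.01, min_comparisons = 3L) {
  x <- as.data.frame(results)
  n_comp <- length(unique(x$comparison_id))
  if (n_comp < min_comparisons)
    hep_stop("config", "need results from >= %d comparisons, got %d",
             min_comparisons, n_comp)
  key <- paste(x$pathway_id, x$comparison_id, sep = "\r")
  calls <- lapply(split(x, key), function(g) {
    sig <- g[g$p < p_max, , drop = FALSE]
    if (nrow(sig) == 0L) return(NULL)
    best <- sig[which.min(sig$p), , drop = FALSE]
    data.frame(pathway_id = best$pathway_id,
               comparison_id = best$comparison_id,
               direction = best$direction, p = best$p,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  pathways <- sort(unique(x$pathway_id))
  if (is.null(calls)) {
    calls <- data.frame(pathway_id = character(), comparison_id = character(),
                        direction = character(), p = numeric(),
                        stringsAsFactors = FALSE)
  }
  rownames(calls) <- NULL
  tab <- lapply(pathways, function(pid) {
    g <- calls[calls$pathway_id == pid, , drop = FALSE]
    data.frame(pathway_id = pid, n_comparisons_hit = nrow(g),
               n_up = sum(g$direction == "up"),
               n_down = sum(g$direction == "down"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tab)
  out$consensus <- out$n_comparisons_hit >= min_comparisons
  rownames(out) <- NULL
  attr(out, "calls") <- calls
  attr(out, "p_max") <- p_max
  attr(out, "min_comparisons") <- min_comparisons
  class(out) <- c("pathway_consensus", "data.frame")
  out
}

#' @export
print.pathway_consensus <- function(x, ...) {
  cat(sprintf("<pathway_consensus> %d pathways, %d consensus (p<%g in >=%d comparisons)\n",
              nrow(x), sum(x$consensus), attr(x, "p_max"),
              attr(x, "min_comparisons")))
  hit <- as.data.frame(x)[x$consensus, , drop = FALSE]
  if (nrow(hit) > 0L) print.data.frame(hit, digits = 4)
  invisible(x)
}
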