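# Small in-vivo quantifications: qPCR reference-gene normalization, oral
# glucose tolerance test areas under the curve, and Mann-Whitney group
# comparisons.

#' Relative transcript quantity from qPCR Ct values
#'
#' Normalizes a target gene's Ct values to the arithmetic mean Ct of the
#' reference genes: `RQ = 2^(mean(ref Ct) - gene Ct)` per sample (equivalent
#' to the geometric mean of the references' linear quantities under perfect
#' amplification efficiency). The default references are the three
#' housekeeping genes Eef1, Hprt and Gapdh.
#'
#' @param ct_table Data frame with columns `sample`, `gene`, `ct` and
#'   optionally `group`.
#' @param gene Target gene.
#' @param reference_genes Reference gene ids; all must be measured for every
#'   sample in which the target is measured.
#' @return Data frame with one row per sample: `sample`, `group` (if
#'   present), `rq`.
#' @export
qpcr_relative_quantity <- function(ct_table, gene,
                                   reference_genes = c("Eef1", "Hprt", "Gapdh")) {
  need <- c("sample", "gene", "ct")
  if (!all(need %in% names(ct_table)))
    hep_stop("data", "ct_table needs columns %s", paste(need, collapse = ", "))
  if (any(ct_table$ct <= 0, na.rm = TRUE))
    hep_stop("data", "Ct values must be positive")
  tgt <- ct_table[ct_table$gene == gene, , drop = FALSE]
  if (nrow(tgt) == 0L) hep_stop("data", "gene '%s' not measured", gene)
  if (anyDuplicated(tgt$sample))
    hep_stop("data", "gene '%s': duplicated Ct for sample '%s'", gene,
             tgt$sample[duplicated(tgt$sample)][1L])
  rq <- vapply(seq_len(nrow(tgt)), function(i) {
    s <- tgt$sample[i]
    refs <- ct_table[ct_table$sample == s &
                       ct_table$gene %in% reference_genes, , drop = FALSE]
    miss <- setdiff(reference_genes, refs$gene)
    if (length(miss) > 0L || any(is.na(refs$ct)))
      hep_stop("data", "sample '%s': missing reference Ct for gene '%s'",
               s, if (length(miss) > 0L) miss[1L]
                  else refs$gene[is.na(refs$ct)][1L])
    2^(mean(refs$ct) - tgt$ct[i])
  }, numeric(1L))
  out <- data.frame(sample = tgt$sample, rq = rq, stringsAsFactors = FALSE)
  if ("group" %in% names(tgt)) out$group <- tgt$group
  out
}

#' Area under an oral glucose tolerance curve
#'
#' Trapezoidal integral of glucose concentration over time, on the raw
#' values (total AUC, no baseline subtraction). The full 0-120 min window of
#' the assay is the documented convention; the function integrates whatever
#' contiguous window it is given, so AUCs are additive over sub-intervals.
#'
#' @param timepoints Minutes, strictly increasing, length >= 2.
#' @param glucose Glucose in mmol/L at each timepoint, non-negative.
#' @return AUC in mmol/L x min.
#' @export
ogtt_auc <- function(timepoints, glucose) {
  if (length(timepoints) < 2L || length(glucose) != length(timepoints))
    hep_stop("data", "need >= 2 matching timepoints and glucose values")
  if (any(diff(timepoints) <= 0))
    hep_stop("data", "timepoints must be strictly increasing")
  if (any(is.na(glucose)) || any(glucose < 0))
    hep_stop("data", "glucose values must be non-negative and non-missing")
  sum(diff(timepoints) * (utils::head(glucose, -1L) + utils::tail(glucose, -1L)) / 2)
}

#' Mann-Whitney U test for two independent groups
#'
#' `U` is the number of (a, b) pairs with `a > b` (plus half the ties), i.e.
#' the classic Mann-Whitney statistic for the first group. The two-sided p-value is exact (full enumeration of group
#' labelings) when the combined sample size is at most 20 and there are no
#' ties, and a tie-corrected normal approximation with continuity correction
#' otherwise.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact computation;
#'   default `NULL` applies the rule above.
#' @return List with `U`, `p` (two-sided) and `method`.
#' @export
mann_whitney <- function(group_a, group_b, exact = NULL) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    hep_stop("data", "each group needs >= 2 observations")
  if (any(is.na(group_a)) || any(is.na(group_b)))
    hep_stop("data", "missing values are not supported")
  ties <- any(duplicated(c(group_a, group_b)))
  if (is.null(exact))
    exact <- !ties && (length(group_a) + length(group_b)) <= 20L
  if (exact && ties)
    hep_stop("data", "exact p-value is not defined with ties")
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation (tie/continuity corrected)")
}

#' Two-group summary with Mann-Whitney p-value
#'
#' Median and interquartile range per group plus the Mann-Whitney two-sided
#' p-value — the summary the figures of this kind of study print.
#'
#' @param values Numeric measurements.
#' @param group Two-level grouping vector parallel to `values`.
#' @return Data frame with one row per group (`group`, `n`, `median`, `q1`,
#'   `q3`) and attribute `p` (Mann-Whitney two-sided p-value).
#' @export
group_summary <- function(values, group) {
  group <- as.character(group)
  levels_ <- unique(group)
  if (length(levels_) != 2L)
    hep_stop("data", "group_summary expects exactly two groups, got %d",
             length(levels_))
  out <- do.call(rbind, lapply(levels_, function(g) {
    v <- values[group == g]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(v), median = q[2L], q1 = q[1L],
               q3 = q[3L], stringsAsFactors = FALSE)
  }))
  attr(out, "p") <- mann_whitney(values[group == levels_[1L]],
                                 values[group == levels_[2L]])$p
  out
}
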