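# Per-comparison two-group differential expression with empirical-Bayes
# moderated t-statistics. The gene-wise model is the standard one: pooled
# two-group residual variance s2_g on d = nA + nB - 2 df, a scaled
# inverse-chi-squared prior (d0, s0^2) estimated from the marginal
# distribution of the s2_g by moment matching on log s2, posterior variance
# s2_post = (d0 s0^2 + d s2_g) / (d0 + d), and a t-statistic on d0 + d df.

# Solve trigamma(x) = y by Newton iteration on 1/trigamma (monotone,
# well-conditioned). y must be positive.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (-dif / x < 1e-10) break
  }
  x
}

#' Estimate the variance prior from gene-wise sample variances
#'
#' Fits the scaled-F marginal model `s2 ~ s0^2 F(d, d0)` by matching the mean
#' and variance of `log(s2)` to their theoretical values (digamma/trigamma
#' moments). `d0` is clamped to `[0.1, 1e6]`.
#'
#' @param s2 Gene-wise residual variances (zeros and non-finite values are
#'   excluded from estimation).
#' @param d Residual degrees of freedom of each variance (scalar).
#' @return List with `d0` (prior df) and `s0_sq` (prior variance).
#' @export
estimate_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L)
    hep_stop("processing", "need >= 2 positive residual variances to fit the prior")
  z <- log(s2[ok])
  evar <- stats::var(z) - trigamma(d / 2)
  d0 <- if (is.na(evar) || evar <= 0) 1e6 else 2 * trigamma_inverse(evar)
  d0 <- min(max(d0, 0.1), 1e6)
  s0_sq <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Fit one two-group comparison with a moderated t-statistic
#'
#' For each gene, `logFC = mean(group B) - mean(group A)` on the log2 scale,
#' with an empirical-Bayes moderated t-test: the pooled residual variance is
#' shrunk toward a prior estimated across genes, and inference uses
#' `d0 + d` degrees of freedom. Genes with any missing value among the
#' comparison's samples are excluded from this comparison only.
#'
#' @param study An [expression_study()] on log2 scale.
#' @param spec A [comparison_spec()]; its samples must exist in the study.
#' @param d0 Optional prior df override. `d0 = 0` disables moderation and
#'   reduces every gene to the ordinary pooled two-sample t-test; `Inf`-like
#'   values shrink every variance to the prior. `NULL` (default) estimates
#'   the prior from the data.
#' @param s0_sq Optional prior variance override (only used with a non-`NULL`
#'   positive `d0`).
#' @param conf_level Confidence level for the logFC interval.
#' @return A data frame of class `de_result` with one row per analyzed gene:
#'   `gene`, `logfc`, `avg_expr`, `t`, `p`, `ci_low`, `ci_high`, `df_total`,
#'   plus a Benjamini-Hochberg `p_adj` column (informational; the consensus
#'   rules consume raw p-values). Attributes: `comparison_id`, `d0`, `s0_sq`,
#'   `n_a`, `n_b`.
#' @export
fit_comparison <- function(study, spec, d0 = NULL, s0_sq = NULL,
                           conf_level = 0.95) {
  if (!inherits(study, "expression_study"))
    hep_stop("config", "study must be an expression_study")
  if (study$scale != "log2")
    hep_stop("config", "differential expression requires log2-scale data")
  ga <- spec$group_a_samples; gb <- spec$group_b_samples
  missing <- setdiff(c(ga, gb), colnames(study$matrix))
  if (length(missing) > 0L)
    hep_stop("config", "comparison '%s': sample '%s' not in study '%s'",
             spec$comparison_id, missing[1L], study$study_id)
  if (length(ga) < 2L || length(gb) < 2L)
    hep_stop("config", "comparison '%s': each group needs >= 2 samples",
             spec$comparison_id)
  xa <- study$matrix[, ga, drop = FALSE]
  xb <- study$matrix[, gb, drop = FALSE]
  complete <- rowSums(is.na(xa)) == 0L & rowSums(is.na(xb)) == 0L
  xa <- xa[complete, , drop = FALSE]
  xb <- xb[complete, , drop = FALSE]
  if (nrow(xa) == 0L)
    hep_stop("processing", "comparison '%s': no gene has complete data",
             spec$comparison_id)
  na <- length(ga); nb <- length(gb)
  d <- na + nb - 2L
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  logfc <- mb - ma
  avg_expr <- (na * ma + nb * mb) / (na + nb)
  ssa <- rowSums((xa - ma)^2)
  ssb <- rowSums((xb - mb)^2)
  s2 <- (ssa + ssb) / d
  if (all(s2 == 0))
    hep_stop("processing", "comparison '%s': zero residual variance for all genes",
             spec$comparison_id)
  if (is.null(d0)) {
    prior <- estimate_variance_prior(s2, d)
    d0 <- prior$d0; s0_sq <- prior$s0_sq
  } else if (d0 > 0 && is.null(s0_sq)) {
    s0_sq <- estimate_variance_prior(s2, d)$s0_sq
  }
  if (d0 > 0) {
    s2_post <- (d0 * s0_sq + d * s2) / (d0 + d)
  } else {
    s2_post <- s2
    s0_sq <- NA_real_
  }
  df_total <- d0 + d
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  t_mod <- ifelse(se > 0, logfc / se, ifelse(logfc == 0, 0, sign(logfc) * Inf))
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  qcrit <- stats::qt(1 - (1 - conf_level) / 2, df = df_total)
  res <- data.frame(
    gene = rownames(xa), logfc = logfc, avg_expr = avg_expr, t = t_mod,
    p = p, ci_low = logfc - qcrit * se, ci_high = logfc + qcrit * se,
    df_total = df_total, p_adj = stats::p.adjust(p, method = "BH"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "comparison_id") <- spec$comparison_id
  attr(res, "study_id") <- spec$study_id
  attr(res, "d0") <- d0
  attr(res, "s0_sq") <- s0_sq
  attr(res, "n_a") <- na
  attr(res, "n_b") <- nb
  class(res) <- c("de_result", "data.frame")
  res
}

#' @export
print.de_result <- function(x, n = 6L, ...) {
  cat(sprintf("<de_result> %s: %d genes (n=%d vs %d; d0=%.3g, s0^2=%.3g)\n",
              attr(x, "comparison_id"), nrow(x), attr(x, "n_a"),
              attr(x, "n_b"), attr(x, "d0"), attr(x, "s0_sq")))
  print.data.frame(utils::head(x[order(x$p), ], n), digits = 4)
  invisible(x)
}

#' @export
summary.de_result <- function(object, p_max = 0.05, logfc_min = 0.1, ...) {
  up <- sum(object$p < p_max & object$logfc > logfc_min)
  down <- sum(object$p < p_max & object$logfc < -logfc_min)
  out <- list(comparison_id = attr(object, "comparison_id"),
              n_genes = nrow(object), n_up = up, n_down = down,
              d0 = attr(object, "d0"), s0_sq = attr(object, "s0_sq"))
  class(out) <- "summary.de_result"
  out
}

#' @export
print.summary.de_result <- function(x, ...) {
  cat(sprintf("%s: %d genes, %d up / %d down at the gates; d0=%.3g s0^2=%.3g\n",
              x$comparison_id, x$n_genes, x$n_up, x$n_down, x$d0, x$s0_sq))
  invisible(x)
}

#' Volcano plot of a differential-expression result
#' @param x A `de_result`.
#' @param p_max,logfc_min Gates used to highlight qualifying genes.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.de_result <- function(x, p_max = 0.05, logfc_min = 0.1, ...) {
  hit <- x$p < p_max & abs(x$logfc) > logfc_min
  graphics::plot(x$logfc, -log10(x$p), pch = 20, cex = 0.5,
                 col = ifelse(hit, "firebrick", "grey60"),
                 xlab = "log2 fold change", ylab = "-log10 p",
                 main = attr(x, "comparison_id"), ...)
  graphics::abline(v = c(-logfc_min, logfc_min), h = -log10(p_max),
                   lty = 3, col = "grey40")
  invisible(x)
}

#' Write a differential-expression result as TSV
#' @param result A `de_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_result <- function(result, path) {
  write_tsv(as.data.frame(result), path)
}

#' Type-I error calibration of the moderated t-test
#'
#' Generates a null cohort (no planted genes) from the design, fits every
#' comparison, and reports the fraction of gene-level p-values below `alpha`
#' together with its binomial standard error. With a correctly calibrated
#' test the rate matches `alpha`.
#'
#' @param design A [simulation_design()] with no planted genes.
#' @param alpha Significance level.
#' @return List with `rejection_rate`, `se` (binomial standard error), and
#'   `n_tests`.
#' @export
type1_calibration <- function(design, alpha = 0.05) {
  if (!is.null(design$planted_genes) && nrow(design$planted_genes) > 0L)
    hep_stop("config", "type-I calibration requires a design with no planted genes")
  cohort <- generate_expression_studies(design)
  pvals <- unlist(lapply(cohort$comparisons, function(cs) {
    fit_comparison(cohort$studies[[cs$study_id]], cs)$p
  }), use.names = FALSE)
  rate <- mean(pvals < alpha)
  list(rejection_rate = rate,
       se = sqrt(rate * (1 - rate) / length(pvals)),
       n_tests = length(pvals))
}
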