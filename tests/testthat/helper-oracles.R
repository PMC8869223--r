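# Independent oracles and small fixture factories used across the suite.

# Exhaustive-enumeration hypergeometric upper tail: genes 1..K are pathway
# members; enumerate every possible selection of size n out of N.
hyper_enum <- function(k, n, K, N) {
  if (n == 0L) return(as.numeric(k <= 0L))
  sel <- utils::combn(N, n)
  mean(colSums(sel <= K) >= k)
}

# Closed-form chi-squared survival for Fisher's combination of k = 2
# p-values: exp(-X/2) * (1 + X/2).
fisher_closed_k2 <- function(p1, p2) {
  x <- -2 * (log(p1) + log(p2))
  exp(-x / 2) * (1 + x / 2)
}

# Plain pooled two-sample t-test oracle (group B minus group A).
plain_t_oracle <- function(a, b) {
  tt <- stats::t.test(b, a, var.equal = TRUE)
  list(logfc = unname(tt$estimate[1L] - tt$estimate[2L]),
       t = unname(tt$statistic), p = tt$p.value)
}

# Exact two-sided Mann-Whitney p by enumerating all group labelings.
mw_enum <- function(a, b) {
  ab <- c(a, b)
  n <- length(a)
  r <- rank(ab)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  labs <- utils::combn(length(ab), n)
  us <- apply(labs, 2L, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Minimal de_result-shaped object for consensus-stage tests.
fake_de <- function(comparison_id, study_id, gene, logfc, p) {
  res <- data.frame(gene = gene, logfc = logfc, avg_expr = 7,
                    t = sign(logfc), p = p, ci_low = logfc - 1,
                    ci_high = logfc + 1, df_total = 10, p_adj = p,
                    stringsAsFactors = FALSE)
  attr(res, "comparison_id") <- comparison_id
  attr(res, "study_id") <- study_id
  attr(res, "d0") <- 4; attr(res, "s0_sq") <- 1
  attr(res, "n_a") <- 3L; attr(res, "n_b") <- 3L
  class(res) <- c("de_result", "data.frame")
  res
}

spec_for <- function(comparison_id, study_id) {
  comparison_spec(comparison_id, study_id,
                  group_a_samples = paste0(comparison_id, "_a", 1:3),
                  group_b_samples = paste0(comparison_id, "_b", 1:3))
}

# Design matching the planted-recovery study conditions: 5 studies x 2
# comparisons, 20 planted genes at |logFC| 0.5 in 4 comparisons, n = 8/group.
recovery_design <- function(seed, n_genes = 2000L, n_planted = 20L,
                            logfc = 0.5, n_comparisons = 4L, ...) {
  simulation_design(
    n_studies = 5L, comparisons_per_study = 2L, n_genes = n_genes,
    n_samples_per_group = 8L,
    planted_genes = data.frame(gene = NA, logfc = rep(logfc, n_planted),
                               n_comparisons = n_comparisons),
    seed = seed, ...
  )
}

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

fit_all <- function(cohort, ...) {
  lapply(cohort$comparisons, function(cs)
    fit_comparison(cohort$studies[[cs$study_id]], cs, ...))
}
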