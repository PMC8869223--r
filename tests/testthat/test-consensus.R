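test_that("Fisher combination: identity at k=1, closed form at k=2, null at all-ones", {
  for (p in c(0.001, 0.05, 0.5, 1)) {
    expect_equal(fisher_combine(p), p, tolerance = 1e-12)
  }
  expect_equal(fisher_combine(c(1, 1)), 1, tolerance = 1e-12)
  expect_equal(fisher_combine(c(0.05, 0.05)),
               fisher_closed_k2(0.05, 0.05), tolerance = 1e-12)
  expect_equal(fisher_combine(c(0.05, 0.05)), 0.0025 * (1 - 4 * log(0.05) / 2),
               tolerance = 1e-12)
  expect_equal(round(fisher_combine(c(0.05, 0.05)), 5), 0.01748)
  expect_error(fisher_combine(numeric()), class = "hepmeta_data_error")
  expect_error(fisher_combine(c(0.5, 0)), class = "hepmeta_data_error")
  expect_error(fisher_combine(c(0.5, 1.2)), class = "hepmeta_data_error")
})

test_that("Fisher combination is monotone in each component", {
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(2:6, 1), 0.001, 1)
    j <- sample(length(p), 1)
    p2 <- p
    p2[j] <- p[j] * runif(1)
    expect_lte(fisher_combine(p2), fisher_combine(p))
  }
})

consensus_fixture <- function() {
  # three comparisons in study S1, two in study S2
  specs <- list(spec_for("S1_c1", "S1"), spec_for("S1_c2", "S1"),
                spec_for("S1_c3", "S1"), spec_for("S2_c1", "S2"),
                spec_for("S2_c2", "S2"))
  genes <- c("gA", "gB", "gC", "gD")
  # gA: up in 3 comparisons of one study (first clause)
  # gB: up in 2 comparisons of 2 studies (second clause)
  # gC: significant p but |logFC| below the gate -> never qualifies
  # gD: nothing
  lfc <- list(
    S1_c1 = c(gA = 0.5, gB = 0.4, gC = 0.05, gD = 0.01),
    S1_c2 = c(gA = 0.6, gB = 0.0, gC = -0.05, gD = 0.01),
    S1_c3 = c(gA = 0.4, gB = 0.0, gC = 0.05, gD = 0.01),
    S2_c1 = c(gA = 0.0, gB = 0.3, gC = 0.05, gD = 0.01),
    S2_c2 = c(gA = 0.0, gB = 0.0, gC = 0.05, gD = 0.01))
  p <- list(
    S1_c1 = c(gA = 0.01, gB = 0.02, gC = 0.04, gD = 0.9),
    S1_c2 = c(gA = 0.01, gB = 0.9, gC = 0.04, gD = 0.9),
    S1_c3 = c(gA = 0.01, gB = 0.9, gC = 0.04, gD = 0.9),
    S2_c1 = c(gA = 0.9, gB = 0.03, gC = 0.04, gD = 0.9),
    S2_c2 = c(gA = 0.9, gB = 0.9, gC = 0.04, gD = 0.9))
  results <- lapply(names(lfc), function(cid) {
    sid <- sub("_c\\d$", "", cid)
    fake_de(cid, sid, genes, unname(lfc[[cid]]), unname(p[[cid]]))
  })
  list(results = results, specs = specs)
}

test_that("consensus clauses: three conditions, or two independent studies", {
  fx <- consensus_fixture()
  rec <- build_consensus(fx$results, fx$specs)
  rec <- rec[match(c("gA", "gB", "gC", "gD"), rec$gene), ]
  expect_identical(rec$consensus, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(rec$n_up, c(3L, 2L, 0L, 0L))
  expect_identical(rec$n_studies_hit, c(1L, 2L, 0L, 0L))
  expect_identical(rec$n_measured, rep(5L, 4))
  # median |logFC| over qualifying comparisons only
  expect_equal(rec$median_abs_logfc[1], 0.5)
  expect_equal(rec$median_abs_logfc[2], 0.35)
  expect_equal(rec$median_abs_logfc[3], 0)
  # Fisher combines over all measured comparisons
  expect_equal(rec$fisher_p[1], fisher_combine(c(0.01, 0.01, 0.01, 0.9, 0.9)),
               tolerance = 1e-12)
})

test_that("a gene down-regulated with small p counts in n_down, not n_up", {
  r1 <- fake_de("c1", "S1", c("g1", "g2"), c(-0.5, 0.5), c(0.01, 0.01))
  r2 <- fake_de("c2", "S2", c("g1", "g2"), c(-0.4, -0.4), c(0.01, 0.01))
  rec <- build_consensus(list(r1, r2), list(spec_for("c1", "S1"),
                                            spec_for("c2", "S2")))
  g1 <- rec[rec$gene == "g1", ]
  expect_identical(c(g1$n_up, g1$n_down), c(0L, 2L))
  expect_true(g1$consensus)  # two distinct studies
  g2 <- rec[rec$gene == "g2", ]
  expect_identical(c(g2$n_up, g2$n_down), c(1L, 1L))
})

test_that("consensus records are invariant to the order of the DE results", {
  fx <- consensus_fixture()
  rec1 <- build_consensus(fx$results, fx$specs)
  rec2 <- build_consensus(rev(fx$results), rev(fx$specs))
  expect_equal(as.data.frame(rec1), as.data.frame(rec2))
})

test_that("ranking sorts on count, then median |logFC|, then Fisher p, then gene", {
  rec <- data.frame(
    gene = c("Vegfb", "Egfr", "Pparg", "Zed", "Abc"),
    n_up = c(3L, 3L, 0L, 1L, 1L),
    n_down = c(0L, 0L, 3L, 0L, 0L),
    n_measured = 10L, n_studies_hit = 2L,
    median_abs_logfc = c(0.263, 0.418, 0.268, 0.1, 0.1),
    fisher_p = c(3e-9, 2.1e-8, 1.8e-3, 0.5, 0.5),
    annotated = TRUE, consensus = TRUE, stringsAsFactors = FALSE)
  ranked <- rank_consensus(rec)
  expect_identical(ranked$gene, c("Egfr", "Pparg", "Vegfb", "Abc", "Zed"))
  expect_identical(rank_consensus(rec, top_n = 1)$gene, "Egfr")
  single <- rank_consensus(rec[2, ])
  expect_identical(single$gene, "Egfr")
})

test_that("genes of interest are validated or reported absent", {
  fx <- consensus_fixture()
  rec <- build_consensus(fx$results, fx$specs)
  goi <- data.frame(gene = c("gA", "gC", "gZ"), note = "")
  tab <- validate_genes_of_interest(goi, rec, min_datasets = 3)
  expect_identical(tab$status, c("measured", "measured", "absent"))
  expect_identical(tab$validated, c(TRUE, FALSE, NA))
  expect_true(is.na(tab$n_up[3]))
  expect_error(validate_genes_of_interest(goi[0, ], rec),
               class = "hepmeta_config_error")
})

test_that("planted consensus genes are recovered against a plain-t oracle pipeline", {
  d <- recovery_design(seed = 101, n_genes = 800)
  co <- generate_expression_studies(d)
  # oracle route: unmoderated gene-wise t-tests, direct application of the
  # replication rule
  oracle_results <- fit_all(co, d0 = 0)
  rec <- build_consensus(oracle_results, co$comparisons)
  flagged <- rec$gene[rec$consensus]
  truth <- co$truth$consensus_gene_ids
  expect_gte(mean(truth %in% flagged), 0.9)
})

test_that("null flagged-gene count matches the binomial prediction", {
  # ten single-comparison studies so per-gene qualifications are independent
  d <- simulation_design(n_studies = 10, comparisons_per_study = 1,
                         n_genes = 3000, n_samples_per_group = 8, seed = 47)
  co <- generate_expression_studies(d)
  results <- fit_all(co)
  # laxer gates so the expected count is appreciably non-zero
  rec <- build_consensus(results, co$comparisons, logfc_min = 0.005,
                         p_max = 0.2, min_conditions = 3, min_studies = 2)
  qual_rate <- mean(unlist(lapply(results, function(r)
    (r$p < 0.2) & (abs(r$logfc) > 0.005))))
  # with every comparison in its own study the rule reduces to >= 2 hits
  p_flag <- 1 - pbinom(1, 10, qual_rate)
  expected <- 3000 * p_flag
  observed <- sum(rec$consensus)
  expect_lt(abs(observed - expected), 4 * sqrt(expected))
})
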