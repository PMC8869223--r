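test_that("design validation rejects impossible plantings", {
  expect_error(
    simulation_design(n_studies = 2, comparisons_per_study = 2,
                      planted_genes = data.frame(gene = NA, logfc = 1,
                                                 n_comparisons = 5)),
    class = "hepmeta_config_error")
  expect_error(
    simulation_design(n_genes = 10,
                      planted_genes = data.frame(gene = "nope", logfc = 1,
                                                 n_comparisons = 1)),
    class = "hepmeta_config_error")
  expect_error(simulation_design(variance_prior = c(d0 = 0, s0_sq = 1)),
               class = "hepmeta_config_error")
  expect_error(
    simulation_design(planted_pathways = list(
      list(pathway_id = "P", members = 5, direction = "sideways"))),
    class = "hepmeta_config_error")
})

test_that("a design with no planted genes yields a null cohort, deterministically", {
  d <- simulation_design(n_studies = 2, comparisons_per_study = 1,
                         n_genes = 50, n_samples_per_group = 3, seed = 42)
  co1 <- generate_expression_studies(d)
  co2 <- generate_expression_studies(d)
  expect_length(co1$truth$consensus_gene_ids, 0)
  expect_true(all(co1$truth$true_logfc == 0))
  expect_identical(co1$studies[["SYN01"]]$matrix, co2$studies[["SYN01"]]$matrix)
  expect_identical(co1$studies[["SYN02"]]$matrix, co2$studies[["SYN02"]]$matrix)
})

test_that("planted genes carry their logFC in exactly the stated number of comparisons", {
  d <- recovery_design(seed = 3, n_genes = 400, n_planted = 10)
  co <- generate_expression_studies(d)
  tl <- co$truth$true_logfc
  planted <- co$truth$planted_genes$gene
  expect_identical(unname(rowSums(tl[planted, ] != 0)), rep(4, 10))
  expect_true(all(tl[planted, ][tl[planted, ] != 0] == 0.5))
  expect_true(all(rowSums(tl[setdiff(rownames(tl), planted), ] != 0) == 0))
})

test_that("mean observed logFC of planted genes converges to the planted value", {
  d <- simulation_design(
    n_studies = 5, comparisons_per_study = 2, n_genes = 1000,
    n_samples_per_group = 20,
    planted_genes = data.frame(gene = NA, logfc = 0.5,
                               n_comparisons = rep(4, 200)),
    seed = 7)
  co <- generate_expression_studies(d)
  results <- fit_all(co)
  tl <- co$truth$true_logfc
  obs <- unlist(lapply(results, function(r) {
    affected <- rownames(tl)[tl[, attr(r, "comparison_id")] != 0]
    r$logfc[match(affected, r$gene)]
  }))
  expect_lt(abs(mean(obs) - 0.5), 0.05)
})

test_that("gene-wise sample variances follow the scaled inverse-chi-squared prior", {
  d <- simulation_design(n_studies = 1, comparisons_per_study = 1,
                         n_genes = 5000, n_samples_per_group = 8,
                         noise_sd_floor = 0, seed = 5)
  co <- generate_expression_studies(d)
  cs <- co$comparisons[[1]]
  xa <- co$studies[[1]]$matrix[, cs$group_a_samples]
  xb <- co$studies[[1]]$matrix[, cs$group_b_samples]
  df <- ncol(xa) + ncol(xb) - 2
  s2 <- (rowSums((xa - rowMeans(xa))^2) + rowSums((xb - rowMeans(xb))^2)) / df
  # marginally s2 / s0^2 ~ F(d, d0)
  ks <- stats::ks.test(s2 / d$s0_sq, "pf", df1 = df, df2 = d$d0)
  expect_gt(ks$p.value, 0.01)
})

test_that("generated GMT matches the ground truth and is deterministic", {
  d <- simulation_design(
    n_genes = 200, seed = 9,
    planted_pathways = list(list(pathway_id = "PW1", members = 30,
                                 affected_fraction = 0.5, direction = "up")))
  gmt0 <- generate_gmt(d, n_background = 0)
  expect_length(gmt0$sets, 1)
  expect_length(gmt0$sets[["PW1"]], 30)
  expect_identical(generate_gmt(d, n_background = 5)$sets,
                   generate_gmt(d, n_background = 5)$sets)
  # planted members agree with the expression-side truth
  co <- generate_expression_studies(d)
  pw <- co$truth$pathways[["PW1"]]
  expect_setequal(gmt0$sets[["PW1"]], pw$members)
  # exactly ceiling(0.5 * 30) members perturbed, all positive
  tl <- co$truth$true_logfc
  affected <- rownames(tl)[rowSums(tl != 0) > 0]
  expect_length(intersect(affected, pw$members), ceiling(0.5 * 30))
  expect_true(all(tl[pw$affected_genes, pw$affected_comps] > 0))
})

test_that("linear RPKM export inverts the log2 read transform", {
  d <- simulation_design(n_studies = 1, comparisons_per_study = 1,
                         n_genes = 20, n_samples_per_group = 3, seed = 2)
  st <- generate_expression_studies(d)$studies[[1]]
  lin <- as_linear_rpkm(st)
  expect_identical(lin$scale, "linear")
  expect_equal(log2(lin$matrix + 1), st$matrix, tolerance = 1e-12)
})

test_that("generated slides hit the requested vacuole fraction and are reproducible", {
  expect_error(generate_slide(100, 100, vacuole_fraction = 0.7),
               class = "hepmeta_config_error")
  s0 <- generate_slide(160, 160, vacuole_fraction = 0, seed = 1)
  expect_identical(sum(s0$vacuole_mask), 0L)
  s <- generate_slide(320, 320, vacuole_fraction = 0.25, seed = 4)
  expect_lt(abs(sum(s$vacuole_mask) / sum(s$tissue_mask) - 0.25), 0.01)
  s2 <- generate_slide(320, 320, vacuole_fraction = 0.25, seed = 4)
  expect_identical(s$image, s2$image)
  # vacuoles and fibrosis never overlap
  sf <- generate_slide(320, 320, vacuole_fraction = 0.2,
                       fibrosis_fraction = 0.1, seed = 4)
  expect_identical(sum(sf$vacuole_mask & sf$fibrosis_mask), 0L)
})

test_that("cohort writer round-trips through the readers", {
  dir <- withr_local_tempdir()
  d <- recovery_design(seed = 21, n_genes = 120, n_planted = 4)
  co <- generate_expression_studies(d)
  gmt <- generate_gmt(d, n_background = 3)
  paths <- write_cohort(co, gmt, dir)
  st <- read_expression(paths[["expression_SYN01"]], study_id = "SYN01")
  expect_equal(st$matrix, co$studies[["SYN01"]]$matrix, tolerance = 1e-12)
  specs <- read_comparisons(paths[["comparisons"]], studies = co$studies)
  expect_length(specs, 10)
  expect_identical(names(specs), names(co$comparisons))
  gmt2 <- read_gmt(paths[["gmt"]])
  expect_identical(gmt2$sets, gmt$sets)
})
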