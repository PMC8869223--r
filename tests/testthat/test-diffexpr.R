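two_group_study <- function(a, b, genes = sprintf("g%02d", seq_len(nrow(a)))) {
  m <- cbind(a, b)
  dimnames(m) <- list(genes,
                      c(paste0("A", seq_len(ncol(a))), paste0("B", seq_len(ncol(b)))))
  expression_study("S", m)
}

two_group_spec <- function(na, nb) {
  comparison_spec("S_c1", "S", paste0("A", seq_len(na)), paste0("B", seq_len(nb)))
}

test_that("identical groups give logFC 0, t 0, p 1", {
  a <- matrix(rep(c(1, 5, 2, 4), 3), 3, 4, byrow = TRUE)[, 1:4]
  a <- matrix(c(1, 5, 2, 4,
                3, 1, 4, 2,
                0, 2, 1, 3), 3, 4, byrow = TRUE)
  b <- a[, c(3, 1, 4, 2)]  # same values, shuffled
  r <- fit_comparison(two_group_study(a, b), two_group_spec(4, 4))
  expect_equal(r$logfc, rep(0, 3), tolerance = 1e-12)
  expect_equal(r$t, rep(0, 3), tolerance = 1e-12)
  expect_equal(r$p, rep(1, 3), tolerance = 1e-12)
})

test_that("with moderation disabled the fit is the ordinary pooled two-sample t", {
  a <- matrix(c(1, 2, 3), 1, 3)
  b <- matrix(c(3, 4, 5), 1, 3)
  # pad with extra genes so the variance step has company
  a <- rbind(a, matrix(rnorm(9), 3, 3))
  b <- rbind(b, matrix(rnorm(9), 3, 3))
  r <- fit_comparison(two_group_study(a, b), two_group_spec(3, 3), d0 = 0)
  oracle <- plain_t_oracle(c(1, 2, 3), c(3, 4, 5))
  expect_equal(r$logfc[1], 2)
  expect_equal(r$t[1], oracle$t, tolerance = 1e-10)
  expect_equal(r$df_total[1], 4)
  expect_equal(r$p[1], oracle$p, tolerance = 1e-10)
  expect_equal(round(r$p[1], 4), 0.0705)
})

test_that("shrinkage fixed point: s2 = s0_sq leaves the t unmoderated", {
  set.seed(1)
  a <- matrix(rnorm(30), 10, 3)
  b <- matrix(rnorm(30), 10, 3)
  st <- two_group_study(a, b)
  sp <- two_group_spec(3, 3)
  r0 <- fit_comparison(st, sp, d0 = 0)
  r4 <- fit_comparison(st, sp, d0 = 4, s0_sq = 1)
  d <- 4
  s2 <- (rowSums((a - rowMeans(a))^2) + rowSums((b - rowMeans(b))^2)) / d
  # gene-wise identity: posterior variance interpolates s2 and s0_sq
  expect_equal(r4$t, r0$t * sqrt(s2 / ((4 * 1 + d * s2) / (4 + d))),
               tolerance = 1e-10)
  expect_equal(unique(r4$df_total), 8)
  # a gene with s2 exactly 1 is a fixed point
  af <- matrix(c(0, 1, 2), 1, 3); bf <- matrix(c(1, 2, 0), 1, 3)  # s2 = 1
  st2 <- two_group_study(rbind(af, a), rbind(bf, b),
                         genes = sprintf("h%02d", 1:11))
  rf0 <- fit_comparison(st2, sp, d0 = 0)
  rf4 <- fit_comparison(st2, sp, d0 = 4, s0_sq = 1)
  expect_equal(abs(rf4$t[1]), abs(rf0$t[1]), tolerance = 1e-10)
})

test_that("as d0 grows every posterior variance approaches s0_sq", {
  set.seed(2)
  a <- matrix(rnorm(40, sd = 2), 10, 4)
  b <- matrix(rnorm(40, sd = 2), 10, 4)
  st <- two_group_study(a, b)
  r <- fit_comparison(st, two_group_spec(4, 4), d0 = 1e12, s0_sq = 0.5)
  se <- (r$ci_high - r$logfc) / qt(0.975, df = r$df_total)
  s2_post <- se^2 / (1 / 4 + 1 / 4)
  expect_true(all(abs(s2_post - 0.5) < 1e-9))
})

test_that("p-values are invariant to swapping group labels; logFC flips sign", {
  d <- simulation_design(n_studies = 1, comparisons_per_study = 1,
                         n_genes = 200, n_samples_per_group = 5, seed = 8)
  co <- generate_expression_studies(d)
  cs <- co$comparisons[[1]]
  swapped <- comparison_spec("swap", cs$study_id,
                             group_a_samples = cs$group_b_samples,
                             group_b_samples = cs$group_a_samples)
  r1 <- fit_comparison(co$studies[[1]], cs)
  r2 <- fit_comparison(co$studies[[1]], swapped)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$logfc, -r2$logfc, tolerance = 1e-12)
})

test_that("moderated fit agrees with an independent empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  d <- simulation_design(n_studies = 1, comparisons_per_study = 1,
                         n_genes = 500, n_samples_per_group = 6, seed = 13)
  co <- generate_expression_studies(d)
  cs <- co$comparisons[[1]]
  r <- fit_comparison(co$studies[[1]], cs)
  m <- co$studies[[1]]$matrix[, c(cs$group_a_samples, cs$group_b_samples)]
  design <- cbind(1, rep(c(0, 1), each = 6))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(r, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(r, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(r$logfc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(r$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("prior estimation recovers the generating (d0, s0_sq)", {
  d <- simulation_design(n_studies = 1, comparisons_per_study = 1,
                         n_genes = 10000, n_samples_per_group = 8,
                         noise_sd_floor = 0, seed = 17)
  co <- generate_expression_studies(d)
  r <- fit_comparison(co$studies[[1]], co$comparisons[[1]])
  expect_lt(abs(attr(r, "d0") - d$d0) / d$d0, 0.25)
  expect_lt(abs(attr(r, "s0_sq") - d$s0_sq) / d$s0_sq, 0.25)
})

test_that("result invariants hold on simulated fits", {
  d <- recovery_design(seed = 19, n_genes = 300, n_planted = 5)
  co <- generate_expression_studies(d)
  for (r in fit_all(co)) {
    expect_true(all(r$p > 0 & r$p <= 1))
    expect_true(all(r$ci_low <= r$logfc & r$logfc <= r$ci_high))
    nz <- r$logfc != 0
    expect_identical(sign(r$t[nz]), sign(r$logfc[nz]))
  }
})

test_that("degenerate inputs raise the documented errors", {
  m <- matrix(1, 3, 4, dimnames = list(paste0("g", 1:3),
                                       c("A1", "A2", "B1", "B2")))
  st <- expression_study("S", m)
  sp <- comparison_spec("c", "S", c("A1", "A2"), c("B1", "B2"))
  expect_error(fit_comparison(st, sp), class = "hepmeta_processing_error")
  expect_error(
    fit_comparison(st, comparison_spec("c", "S", c("A1", "A2"), c("B1", "zz"))),
    class = "hepmeta_config_error")
  lin <- expression_study("S", m + rnorm(12), scale = "linear",
                          platform = "rnaseq")
  expect_error(fit_comparison(lin, sp), class = "hepmeta_config_error")
})

test_that("type-I calibration endpoints are exact", {
  d <- simulation_design(n_studies = 1, comparisons_per_study = 1,
                         n_genes = 500, n_samples_per_group = 4, seed = 23)
  expect_identical(type1_calibration(d, alpha = 1.000001)$rejection_rate, 1)
  expect_identical(type1_calibration(d, alpha = 0)$rejection_rate, 0)
  dp <- recovery_design(seed = 1, n_genes = 100, n_planted = 2)
  expect_error(type1_calibration(dp), class = "hepmeta_config_error")
})
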