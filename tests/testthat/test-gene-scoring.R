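cs_matrix <- function(n, rho) {
  R <- matrix(rho, n, n)
  diag(R) <- 1
  R
}

test_that("effective test count follows the eigenvalue spectrum", {
  expect_equal(meff(diag(10)), 10L)
  expect_equal(meff(cs_matrix(10, 1)), 1L)
  two_blocks <- as.matrix(Matrix::bdiag(cs_matrix(5, 1), cs_matrix(5, 1)))
  expect_equal(meff(two_blocks), 2L)
  expect_error(meff(matrix(c(1, 0.5, 0.1, 1), 2, 2)), "symmetric")
})

test_that("top-SNP gene model applies the Sidak correction through Meff", {
  expect_equal(gene_p_top(0.01, matrix(1)), 0.01)
  expect_equal(gene_p_top(c(0.01, runif(9, 0.02, 1)), diag(10)),
               1 - 0.99^10, tolerance = 1e-12)
  expect_equal(gene_p_top(rep(0.01, 10), cs_matrix(10, 1)), 0.01,
               tolerance = 1e-12)
  expect_error(gene_p_top(numeric(0), diag(1)), "no SNPs")
})

test_that("mean-SNP gene model reduces to exact chi-square tails", {
  expect_equal(gene_p_mean(1.96, matrix(1)),
               pchisq(1.96^2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(gene_p_mean(1.96, matrix(1)), 0.05, tolerance = 1e-3)
  z <- c(0.5, -1.2, 2.1, 0.3)
  expect_equal(gene_p_mean(z, diag(4)),
               pchisq(sum(z^2), 4, lower.tail = FALSE), tolerance = 1e-12)
  # 5 SNPs in perfect LD behave as a single SNP
  expect_equal(gene_p_mean(rep(1.7, 5), cs_matrix(5, 1)),
               gene_p_mean(1.7, matrix(1)), tolerance = 1e-10)
})

test_that("combined model interpolates between its parts via rho", {
  expect_equal(gene_p_combined(0.03, 0.03, rho = 1), 0.03, tolerance = 1e-10)
  expect_equal(gene_p_combined(0.05, 0.05, rho = 0), 0.0100,
               tolerance = 1e-3)
  # single-SNP gene: the two models coincide and rho = 1 keeps the p
  p1 <- 2 * pnorm(-1.9)
  expect_equal(gene_p_combined(p1, gene_p_mean(1.9, matrix(1)),
                               R = matrix(1)),
               p1, tolerance = 1e-6)
  expect_warning(gene_p_combined(0.1, 0.1, rho = 0.5, R = NULL,
                                 mc_draws = 50), "noisy")
})

test_that("gene models are monotone when every SNP strengthens", {
  set.seed(1)
  R <- cs_matrix(6, 0.3)
  for (i in 1:20) {
    p <- runif(6, 0.05, 1)
    z <- abs(rnorm(6))
    expect_lte(gene_p_top(p * 0.5, R), gene_p_top(p, R))
    expect_lte(gene_p_mean(z * 1.5, R), gene_p_mean(z, R))
  }
})

test_that("score_genes combines assigned SNPs per gene deterministically", {
  cfg <- synth_config(seed = 41, n_genes = 50)
  g <- gen_gwas(cfg)
  asn <- map_snps_to_genes(g$snps, g$genes)
  r1 <- score_genes(g$snps, asn, ld = g$ld, mc_draws = 300, seed = 2)
  r2 <- score_genes(g$snps, asn, ld = g$ld, mc_draws = 300, seed = 2)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 50)
  expect_true(all(r1$p_top > 0 & r1$p_top <= 1))
  expect_equal(r1$z, qnorm(r1$p_combined, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("competitive test equals the closed-form OLS oracle", {
  set.seed(5)
  n <- 150
  covs <- cbind(c1 = rnorm(n), c2 = runif(n))
  memb <- rep(c(1, 0), c(30, n - 30))
  z <- rnorm(n) + 0.8 * memb + 0.3 * covs[, 1]
  gr <- data.frame(gene_id = sprintf("g%03d", 1:n), z = z)
  got <- competitive_set_test(gr, memb, covs)
  oracle <- bf_ols(z, cbind(1, memb, covs))
  expect_equal(got$beta, oracle$beta[2], tolerance = 1e-8)
  expect_equal(got$se, oracle$se[2], tolerance = 1e-8)
  expect_equal(got$p_competitive,
               pt(oracle$beta[2] / oracle$se[2], oracle$df,
                  lower.tail = FALSE), tolerance = 1e-10)
})

test_that("competitive test flags degenerate designs", {
  gr <- data.frame(gene_id = letters[1:10], z = rep(1.3, 10))
  memb <- rep(c(1, 0), each = 5)
  expect_warning(res <- competitive_set_test(gr, memb), "zero variance")
  expect_equal(res$p_competitive, 1)
  expect_equal(res$beta, 0)
  expect_error(competitive_set_test(gr, rep(1, 10)), "set empty or equals")
  expect_error(competitive_set_test(gr, rep(0, 10)), "set empty or equals")
  gr$z <- rnorm(10)
  covs <- cbind(dup1 = 1:10, dup2 = 1:10)
  expect_error(competitive_set_test(gr, memb, covs), "dup2")
})

test_that("GLS with a non-identity gene correlation is a whitened OLS", {
  set.seed(8)
  n <- 60
  S <- 0.4^abs(outer(1:n, 1:n, "-"))  # AR(1) band correlation
  memb <- rbinom(n, 1, 0.3)
  memb[1] <- 1; memb[2] <- 0
  z <- as.numeric(t(chol(S)) %*% rnorm(n)) + memb
  gr <- data.frame(gene_id = sprintf("g%02d", 1:n), z = z)
  got <- competitive_set_test(gr, memb, gene_corr = S)
  U <- chol(S)
  Xw <- backsolve(U, cbind(1, memb), transpose = TRUE)
  yw <- backsolve(U, z, transpose = TRUE)
  oracle <- bf_ols(yw, Xw)
  expect_equal(got$beta, oracle$beta[2], tolerance = 1e-8)
})

test_that("p-value adjustments match hand-computed step-up values", {
  ps <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjust_pvalues(ps, "bh"), rep(0.04, 4))
  expect_equal(adjust_pvalues(ps, "by"), rep(0.04 * (1 + 1/2 + 1/3 + 1/4), 4),
               tolerance = 1e-12)
  expect_equal(adjust_pvalues(0.001, "bonferroni"), 0.001)
  expect_equal(adjust_pvalues(rep(0.001, 50), "bonferroni"), rep(0.05, 50))
  expect_equal(adjust_pvalues(ps, "bonferroni_meff", meff = 2), ps * 2)
  expect_error(adjust_pvalues(ps, "bonferroni_meff"), "meff")
  shuffled <- sample(runif(30))
  bh <- adjust_pvalues(shuffled, "bh")
  by <- adjust_pvalues(shuffled, "by")
  expect_true(all(bh <= by))
  expect_true(all(diff(bh[order(shuffled)]) >= -1e-15))
})

test_that("dual Bonferroni thresholds reproduce the published arithmetic", {
  thr <- druggable_thresholds(4298, 19870)
  expect_equal(signif(thr$t_druggable, 4), 1.163e-5)
  expect_equal(signif(thr$t_genomewide, 4), 2.516e-6)
  expect_equal(unlist(druggable_thresholds(1, 1), use.names = FALSE),
               c(0.05, 0.05))
  expect_equal(signif(0.05 / 49, 1), 1e-3)
  expect_error(druggable_thresholds(0, 10), ">= 1")
})
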