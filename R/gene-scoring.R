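#' Effective number of independent tests from a correlation matrix
#'
#' The smallest number of leading eigenvalues whose cumulative sum reaches
#' `variance_fraction` of the trace — i.e. the number of principal
#' components explaining 99.5% of the variance by default.  Used both as a
#' Sidak exponent for the top-SNP gene model and to Bonferroni-correct
#' correlated gene-set tests.
#'
#' @param R symmetric correlation matrix (unit diagonal).
#' @param variance_fraction fraction of the trace to capture.
#' @return integer in `[1, nrow(R)]`.
#' @export
meff <- function(R, variance_fraction = 0.995) {
  R <- as.matrix(R)
  if (!isSymmetric(unname(R), tol = 1e-8)) stop("R must be symmetric")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  target <- variance_fraction * sum(diag(R))
  m <- which(cumsum(ev) >= target - 1e-12)[1]
  if (is.na(m)) m <- length(ev)
  as.integer(max(1, m))
}

eigenvalues_sym <- function(R)
  eigen(as.matrix(R), symmetric = TRUE, only.values = TRUE)$values

#' Gene p-value from the top SNP (Sidak with an effective test count)
#'
#' `p = 1 - (1 - min p)^Meff(R)`, where the effective number of tests
#' accounts for LD between the gene's SNPs: independent SNPs give the full
#' Sidak correction, perfect LD gives none.
#'
#' @param snp_ps SNP p-values within the gene.
#' @param R SNP correlation (LD) matrix for the gene.
#' @return p-value.
#' @export
gene_p_top <- function(snp_ps, R) {
  if (length(snp_ps) == 0) stop("no SNPs in gene")
  if (length(snp_ps) != nrow(as.matrix(R)))
    stop("R dimension does not match SNP count")
  m <- meff(R)
  -expm1(m * log1p(-min(snp_ps)))
}

#' Gene p-value from the mean SNP statistic (Satterthwaite approximation)
#'
#' The sum of squared SNP Z-scores has null distribution
#' \eqn{\sum_j \lambda_j \chi^2_1} with \eqn{\lambda} the eigenvalues of the
#' LD matrix; the tail is evaluated by Satterthwaite moment matching with a
#' scaled chi-square (exact when the eigenvalues are equal, e.g. independent
#' SNPs or a single block of perfect LD).
#'
#' @param snp_zs SNP Z-scores within the gene.
#' @param R SNP correlation (LD) matrix for the gene.
#' @return p-value.
#' @export
gene_p_mean <- function(snp_zs, R) {
  if (length(snp_zs) == 0) stop("no SNPs in gene")
  if (length(snp_zs) != nrow(as.matrix(R)))
    stop("R dimension does not match SNP count")
  lam <- pmax(eigenvalues_sym(R), 0)
  T_stat <- sum(snp_zs^2)
  s <- sum(lam^2) / sum(lam)   # scale
  g <- sum(lam)^2 / sum(lam^2) # degrees of freedom
  pchisq(T_stat / s, df = g, lower.tail = FALSE)
}

#' Null correlation between the top and mean gene models
#'
#' Seeded Monte-Carlo estimate: SNP Z-scores are drawn from MVN(0, R) and
#' pushed through both gene models; the correlation of the two probit scores
#' is returned.  Used by [gene_p_combined()] to calibrate the Stouffer
#' combination.
#'
#' @param R SNP correlation matrix.
#' @param mc_draws number of Monte-Carlo draws.
#' @param seed RNG seed.
#' @return correlation in `[-1, 1]`.
#' @export
top_mean_null_cor <- function(R, mc_draws = 1000, seed = 1) {
  R <- as.matrix(R)
  n <- nrow(R)
  if (n == 1) return(1)
  e <- eigen(R, symmetric = TRUE)
  A <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  m <- meff(R)
  lam <- pmax(e$values, 0)
  s <- sum(lam^2) / sum(lam)
  g <- sum(lam)^2 / sum(lam^2)
  withr::with_seed(seed, {
    Z <- matrix(rnorm(mc_draws * n), mc_draws, n) %*% A
    P <- 2 * pnorm(-abs(Z))
    p_top <- -expm1(m * log1p(-apply(P, 1, min)))
    p_mean <- pchisq(rowSums(Z^2) / s, df = g, lower.tail = FALSE)
    r <- cor(probit_upper(p_top), probit_upper(p_mean))
    if (!is.finite(r)) r <- 1
    min(max(r, -0.999), 1)
  })
}

#' Combine the top and mean gene models into one gene p-value
#'
#' Stouffer combination of the two probit scores with a correlation-aware
#' denominator: `Z = (z_top + z_mean) / sqrt(2 + 2 rho)`, where `rho` is the
#' null correlation of the two models (estimated by seeded Monte-Carlo from
#' the gene's LD matrix unless supplied).
#'
#' @param p_top,p_mean p-values from [gene_p_top()] and [gene_p_mean()].
#' @param R SNP correlation matrix (needed when `rho` is NULL).
#' @param rho optional known null correlation; skips the Monte-Carlo step.
#' @param mc_draws Monte-Carlo draws for the correlation estimate
#'   (a warning is issued below 100).
#' @param seed RNG seed for the Monte-Carlo estimate.
#' @return combined p-value.
#' @export
gene_p_combined <- function(p_top, p_mean, R = NULL, rho = NULL,
                            mc_draws = 1000, seed = 1) {
  if (mc_draws < 100) warning("mc_draws < 100: correlation estimate is noisy")
  if (is.null(rho)) {
    if (is.null(R)) stop("either R or rho must be supplied")
    rho <- top_mean_null_cor(R, mc_draws = mc_draws, seed = seed)
  }
  z <- (probit_upper(p_top) + probit_upper(p_mean)) / sqrt(2 + 2 * rho)
  pnorm(z, lower.tail = FALSE)
}

#' Score every gene from assigned SNP statistics
#'
#' Computes the top, mean and combined gene models for each gene in the
#' SNP-to-gene assignment.  Genes with no LD matrix supplied are treated as
#' having independent SNPs.  Monte-Carlo calibration of the combined model
#' is cached per distinct LD matrix, so exchangeable-LD designs pay for it
#' once.
#'
#' @param snps summary-statistics data frame (snp_id, p, and optionally z,
#'   maf).  When `z` is absent, `|z|` is recovered from the two-sided p.
#' @param assignment SNP-to-gene table from [map_snps_to_genes()].
#' @param ld optional named list (gene_id -> LD matrix with SNP-id
#'   dimnames); subset to the assigned SNPs per gene.
#' @param mc_draws,seed Monte-Carlo settings for [top_mean_null_cor()].
#' @return data frame with gene_id, n_snps, p_top, p_mean, p_combined and
#'   z = probit(1 - p_combined).
#' @export
score_genes <- function(snps, assignment, ld = NULL, mc_draws = 1000,
                        seed = 1) {
  idx <- match(assignment$snp_id, snps$snp_id)
  keep <- !is.na(idx)
  assignment <- assignment[keep, , drop = FALSE]
  idx <- idx[keep]
  p <- snps$p[idx]
  z <- if (!is.null(snps$z)) abs(snps$z[idx]) else qnorm(p / 2, lower.tail = FALSE)
  by_gene <- split(seq_along(idx), assignment$gene_id)
  cache <- new.env(parent = emptyenv())
  ng <- length(by_gene)
  gene_id <- names(by_gene)
  n_snps <- integer(ng)
  p_top <- p_mean <- p_comb <- numeric(ng)
  for (gi in seq_len(ng)) {
    ii <- by_gene[[gi]]
    n <- length(ii)
    R <- diag(n)
    if (!is.null(ld) && !is.null(ld[[gene_id[gi]]])) {
      Rg <- ld[[gene_id[gi]]]
      if (!is.null(dimnames(Rg))) {
        ids <- intersect(rownames(Rg), assignment$snp_id[ii])
        if (length(ids) == n) {
          R <- Rg[assignment$snp_id[ii], assignment$snp_id[ii]]
        } else if (length(ids) > 0) {
          ii <- ii[match(ids, assignment$snp_id[ii])]
          n <- length(ii)
          R <- Rg[ids, ids, drop = FALSE]
        }
      } else if (nrow(Rg) == n) R <- Rg
    }
    R <- as.matrix(R)
    key <- paste(c(n, signif(as.numeric(R), 8)), collapse = ",")
    stats_R <- cache[[key]]
    if (is.null(stats_R)) {
      lam <- pmax(eigenvalues_sym(R), 0)
      stats_R <- list(
        m = meff(R), scale = sum(lam^2) / sum(lam),
        df = sum(lam)^2 / sum(lam^2),
        rho = if (n == 1) 1 else top_mean_null_cor(R, mc_draws, seed))
      cache[[key]] <- stats_R
    }
    n_snps[gi] <- n
    p_top[gi] <- -expm1(stats_R$m * log1p(-min(p[ii])))
    p_mean[gi] <- pchisq(sum(z[ii]^2) / stats_R$scale, df = stats_R$df,
                         lower.tail = FALSE)
    p_comb[gi] <- gene_p_combined(p_top[gi], p_mean[gi], rho = stats_R$rho)
  }
  data.frame(gene_id = gene_id, n_snps = n_snps, p_top = p_top,
             p_mean = p_mean, p_combined = p_comb, z = probit_upper(p_comb),
             stringsAsFactors = FALSE)
}

#' Gene-level covariates for the competitive regression
#'
#' Gene size (bp), SNP density, their logs, and a log minor-allele-count
#' proxy (sum of assigned SNP MAFs), matching the confounders the
#' competitive model corrects for.
#'
#' @param gene_results output of [score_genes()].
#' @param genes gene table with start/end.
#' @param snps summary statistics with `maf` (optional; the MAC proxy is
#'   omitted without it).
#' @param assignment SNP-to-gene table.
#' @return numeric matrix with one row per `gene_results` row.
#' @export
gene_covariates <- function(gene_results, genes, snps = NULL,
                            assignment = NULL) {
  gi <- match(gene_results$gene_id, genes$gene_id)
  size <- genes$end[gi] - genes$start[gi] + 1
  density <- gene_results$n_snps / size
  out <- cbind(size = size, log_size = log(size),
               density = density, log_density = log(density))
  if (!is.null(snps) && !is.null(snps$maf) && !is.null(assignment)) {
    maf <- snps$maf[match(assignment$snp_id, snps$snp_id)]
    mac <- tapply(maf, assignment$gene_id, sum, na.rm = TRUE)
    out <- cbind(out, log_mac = log(pmax(
      as.numeric(mac[gene_results$gene_id]), 1e-6)))
  }
  out
}

#' Competitive gene-set association test
#'
#' Generalized least squares regression of the gene Z-scores on set
#' membership plus gene covariates:
#' `Z = b0 + beta * membership + Gamma * covariates`, with error covariance
#' `gene_corr` (identity = OLS).  The one-sided p-value asks whether genes
#' in the set are more strongly associated than genes outside it.
#'
#' @param gene_results output of [score_genes()] (uses the `z` column).
#' @param membership logical or 0/1 vector over the gene universe; must be
#'   neither all 0 nor all 1.
#' @param covariates optional numeric matrix of gene covariates.
#' @param gene_corr optional gene-gene correlation matrix (default identity).
#' @return list with beta, se, t, df, p_competitive, n_set, n_universe.
#' @export
competitive_set_test <- function(gene_results, membership, covariates = NULL,
                                 gene_corr = NULL) {
  y <- gene_results$z
  m <- as.numeric(membership)
  n <- length(y)
  if (length(m) != n) stop("membership length must match gene universe")
  if (all(m == 0) || all(m == 1)) stop("set empty or equals universe")
  X <- cbind(`(Intercept)` = 1, set = m)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  if (!is.null(gene_corr)) {
    U <- chol(gene_corr)
    nms <- colnames(X)
    X <- backsolve(U, X, transpose = TRUE)
    colnames(X) <- nms
    y <- backsolve(U, y, transpose = TRUE)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("singular design; collinear column(s): ", paste(bad, collapse = ", "))
  }
  if (var(gene_results$z) < .Machine$double.eps) {
    warning("zero variance in gene Z-scores; returning p = 1")
    return(list(beta = 0, se = NA_real_, t = NA_real_, df = n - ncol(X),
                p_competitive = 1, n_set = sum(m), n_universe = n))
  }
  fit <- qr.coef(qx, y)
  resid <- y - X %*% fit
  df <- n - ncol(X)
  sigma2 <- sum(resid^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  tval <- fit[["set"]] / se
  list(beta = unname(fit[["set"]]), se = se, t = tval, df = df,
       p_competitive = stats::pt(tval, df = df, lower.tail = FALSE),
       n_set = sum(m), n_universe = n)
}

#' Competitive scan over a collection of gene-sets
#'
#' Runs [competitive_set_test()] for every set in a collection and attaches
#' BH and BY q-values and Bonferroni-adjusted p-values across the scan.
#' Sets with no member in the universe (or covering the whole universe) are
#' skipped with a warning.
#'
#' @param gene_results output of [score_genes()].
#' @param collections named list of gene-id vectors (e.g. drug gene-sets or
#'   pathways).
#' @param covariates optional covariate matrix (see [gene_covariates()]).
#' @param gene_corr optional gene-gene correlation matrix.
#' @return data frame with set_id, n_genes, n_universe, beta,
#'   p_competitive, p_bonf, q_bh, q_by.
#' @export
competitive_scan <- function(gene_results, collections, covariates = NULL,
                             gene_corr = NULL) {
  universe <- gene_results$gene_id
  if (!is.null(covariates)) {
    # drop covariate columns collinear with the intercept or each other,
    # so a degenerate covariate never poisons the whole scan
    X0 <- cbind(1, as.matrix(covariates))
    q0 <- qr(X0)
    if (q0$rank < ncol(X0)) {
      drop_idx <- setdiff(q0$pivot[-seq_len(q0$rank)], 1) - 1L
      warning("dropping collinear covariate(s): ",
              paste(colnames(covariates)[drop_idx], collapse = ", "))
      covariates <- as.matrix(covariates)[, -drop_idx, drop = FALSE]
      if (ncol(covariates) == 0) covariates <- NULL
    }
  }
  rows <- lapply(names(collections), function(id) {
    memb <- universe %in% collections[[id]]
    if (!any(memb) || all(memb)) return(NULL)
    r <- competitive_set_test(gene_results, memb, covariates, gene_corr)
    data.frame(set_id = id, n_genes = r$n_set, n_universe = r$n_universe,
               beta = r$beta, p_competitive = r$p_competitive,
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0)
    warning(skipped, " set(s) skipped (empty in universe or equal to it)")
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable sets in collection")
  out$p_bonf <- adjust_pvalues(out$p_competitive, "bonferroni")
  out$q_bh <- adjust_pvalues(out$p_competitive, "bh")
  out$q_by <- adjust_pvalues(out$p_competitive, "by")
  rownames(out) <- NULL
  out
}

#' Multiple-testing adjustment
#'
#' Bonferroni, Benjamini-Hochberg, Benjamini-Yekutieli, or Bonferroni with
#' an effective number of tests (for correlated hypotheses, see [meff()]).
#'
#' @param ps p-values in (0, 1].
#' @param method one of "bonferroni", "bh", "by", "bonferroni_meff".
#' @param meff effective test count (required for "bonferroni_meff").
#' @return adjusted values.
#' @export
adjust_pvalues <- function(ps, method = c("bonferroni", "bh", "by",
                                          "bonferroni_meff"), meff = NULL) {
  method <- match.arg(method)
  switch(method,
    bonferroni = p.adjust(ps, "bonferroni"),
    bh = p.adjust(ps, "BH"),
    by = p.adjust(ps, "BY"),
    bonferroni_meff = {
      if (is.null(meff)) stop("bonferroni_meff requires meff")
      pmin(1, meff * ps)
    })
}

#' Dual Bonferroni thresholds for druggable-gene selection
#'
#' One threshold for the druggable genome and a stricter one for the whole
#' protein-coding genome (e.g. 0.05/4298 = 1.163e-5 and
#' 0.05/19870 = 2.516e-6); genes are later partitioned by which they pass.
#'
#' @param n_druggable number of druggable genes tested.
#' @param n_protein_coding number of protein-coding genes.
#' @param alpha familywise error rate.
#' @return list with t_druggable and t_genomewide.
#' @export
druggable_thresholds <- function(n_druggable, n_protein_coding, alpha = 0.05) {
  if (n_druggable < 1 || n_protein_coding < 1) stop("counts must be >= 1")
  list(t_druggable = alpha / n_druggable,
       t_genomewide = alpha / n_protein_coding)
}
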