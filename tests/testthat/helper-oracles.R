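# Independent oracles used across the suite: deliberately brute-force and
# kept free of the implementation paths they check.

# AUC by exhaustive pair counting: wins + half credit for ties.
bf_auc_pairs <- function(scores, hits) {
  hs <- scores[hits]
  ns <- scores[!hits]
  u <- 0
  for (a in hs) u <- u + sum(a > ns) + 0.5 * sum(a == ns)
  100 * u / (length(hs) * length(ns))
}

# Betweenness by explicit shortest-path enumeration (BFS path counting).
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  B <- numeric(n)
  bfs <- function(s) {
    d <- rep(Inf, n)
    sigma <- numeric(n)
    d[s] <- 0
    sigma[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nbrs <- which(adj[v, ] > 0)
        for (u in nbrs) {
          if (is.infinite(d[u])) {
            d[u] <- d[v] + 1
            nxt <- c(nxt, u)
          }
          if (d[u] == d[v] + 1) sigma[u] <- sigma[u] + sigma[v]
        }
      }
      frontier <- unique(nxt)
    }
    list(d = d, sigma = sigma)
  }
  info <- lapply(seq_len(n), bfs)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (is.infinite(info[[s]]$d[t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (info[[s]]$d[v] + info[[t]]$d[v] == info[[s]]$d[t])
        B[v] <- B[v] + info[[s]]$sigma[v] * info[[t]]$sigma[v] /
          info[[s]]$sigma[t]
    }
  }
  B
}

# SNP-to-gene assignment by an O(snps x genes) scan with explicit
# strand-aware window arithmetic.
bf_map_snps <- function(snps, genes, up, down) {
  out <- list()
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(genes))) {
      if (sub("^chr", "", snps$chrom[i]) != sub("^chr", "", genes$chrom[j]))
        next
      if (genes$strand[j] == "+") {
        lo <- genes$start[j] - up
        hi <- genes$end[j] + down
      } else {
        lo <- genes$start[j] - down
        hi <- genes$end[j] + up
      }
      if (snps$pos[i] >= lo && snps$pos[i] <= hi)
        out[[length(out) + 1]] <- c(snps$snp_id[i], genes$gene_id[j])
    }
  }
  if (!length(out)) return(data.frame(snp_id = character(0),
                                      gene_id = character(0)))
  m <- do.call(rbind, out)
  data.frame(snp_id = m[, 1], gene_id = m[, 2], stringsAsFactors = FALSE)
}

# Closed-form OLS oracle via explicit normal equations.
bf_ols <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  list(beta = as.numeric(beta), se = as.numeric(se), df = df)
}

# A tiny gene table for interval tests.
toy_genes <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_id = r[[1]], chrom = r[[2]], start = as.numeric(r[[3]]),
               end = as.numeric(r[[4]]), strand = r[[5]],
               stringsAsFactors = FALSE)
  }))
}
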