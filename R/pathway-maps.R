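#' Binary membership matrix for a gene-set collection
#'
#' Encodes each gene-set by gene content as a binary vector over the union
#' of all genes (or a supplied universe).
#'
#' @param sets named list of gene-id vectors.
#' @param universe optional character vector of genes defining the columns.
#' @return binary matrix, sets in rows.
#' @export
membership_matrix <- function(sets, universe = NULL) {
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  M <- matrix(0, length(sets), length(universe),
              dimnames = list(names(sets), universe))
  for (i in seq_along(sets)) M[i, universe %in% sets[[i]]] <- 1
  M
}

#' Tanimoto (Jaccard) similarity matrix between gene-sets
#'
#' `K[i, j] = |A_i intersect A_j| / |A_i union A_j|` over the binary
#' membership vectors; symmetric with unit diagonal.
#'
#' @param M binary membership matrix (sets x genes) or a named list of
#'   gene-sets.
#' @return N x N similarity matrix in `[0, 1]`.
#' @export
tanimoto_matrix <- function(M) {
  if (is.list(M)) M <- membership_matrix(M)
  M <- as.matrix(M)
  sz <- rowSums(M)
  if (any(sz == 0)) {
    empty <- rownames(M)[sz == 0] %||% which(sz == 0)
    stop("empty gene-set(s): ", paste(empty, collapse = ", "))
  }
  inter <- M %*% t(M)
  uni <- outer(sz, sz, "+") - inter
  K <- inter / uni
  diag(K) <- 1
  K
}

center_kernel <- function(K) {
  n <- nrow(K)
  H <- diag(n) - matrix(1 / n, n, n)
  H %*% K %*% H
}

#' Feature-space dimension from a kernel spectrum
#'
#' Number of kernel principal components explaining `variance_fraction`
#' (default 99.5%) of the variance: the kernel is double-centered,
#' eigendecomposed, and the smallest D whose leading nonnegative
#' eigenvalues reach the target mass is returned.  A zero-variance
#' collection (all sets identical) yields D = 1 with a warning.
#'
#' @param K kernel (similarity) matrix.
#' @param variance_fraction fraction of variance to capture.
#' @return integer D >= 1.
#' @export
feature_dim <- function(K, variance_fraction = 0.995) {
  ev <- eigen(center_kernel(as.matrix(K)), symmetric = TRUE,
              only.values = TRUE)$values
  pos <- ev[ev > 1e-10 * max(abs(ev), 1)]
  if (length(pos) == 0) {
    warning("zero variance in kernel (all sets identical); D = 1")
    return(1L)
  }
  as.integer(which(cumsum(pos) >= variance_fraction * sum(pos) - 1e-12)[1])
}

kernel_pca_embed <- function(K, D) {
  e <- eigen(center_kernel(as.matrix(K)), symmetric = TRUE)
  D <- min(D, sum(e$values > 1e-10 * max(abs(e$values), 1)))
  D <- max(D, 1L)
  X <- e$vectors[, seq_len(D), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(D)], 0)), D)
  X
}

grid_2d <- function(k) {
  g <- if (k == 1) 0 else seq(-1, 1, length.out = k)
  as.matrix(expand.grid(x = g, y = g))
}

#' Fit a kernel generative topographic map to a gene-set kernel
#'
#' Realizes kernel GTM as standard GTM on a kernel-PCA embedding: the
#' feature dimension D captures 99.5% of the kernel variance, the latent
#' grid has `k = round(sqrt(N))` nodes per side, the RBF grid
#' `m = round(sqrt(k))` per side (both floored at 2), the RBF width is
#' `w` times the RBF grid spacing, and `l` is the Gaussian weight-decay
#' regularizer.  The EM iteration alternates responsibilities (E-step) with
#' a penalized least-squares update of the mapping and a noise-precision
#' update (M-step); the monitored objective (`loglik` trace) is the data
#' log-likelihood minus the weight penalty, which EM never decreases.
#' Initialization maps the latent grid through the first two principal
#' components, so the fit is deterministic given the seed.
#'
#' @param K Tanimoto kernel from [tanimoto_matrix()] (N >= 4).
#' @param l regularization coefficient (default 1).
#' @param w RBF width factor (default 1).
#' @param seed RNG seed (reserved for tie-breaking; the fit is otherwise
#'   deterministic).
#' @param max_iter,tol EM stopping rule: relative objective change below
#'   `tol` or `max_iter` iterations.
#' @param variance_fraction kernel variance captured by the embedding.
#' @return object of class `kgtm`: list with U (latent nodes), Phi, W,
#'   beta, R (responsibilities, nodes x sets), X (embedding), loglik
#'   (objective trace), loglik_data (unpenalized trace), D, k, m, sigma,
#'   n_iter, converged.
#' @export
kgtm_fit <- function(K, l = 1, w = 1, seed = 1, max_iter = 500, tol = 1e-6,
                     variance_fraction = 0.995) {
  K <- as.matrix(K)
  N <- nrow(K)
  if (N < 4) stop("need at least 4 gene-sets")
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-6 * max(abs(K)))
    stop("kernel is not positive semi-definite")
  D <- feature_dim(K, variance_fraction)
  X <- kernel_pca_embed(K, D)
  D <- ncol(X)
  k <- max(2L, round(sqrt(N)))
  m <- max(2L, round(sqrt(k)))
  U <- grid_2d(k)            # K_nodes x 2 latent grid in [-1,1]^2
  C <- grid_2d(m)            # RBF centers
  sigma <- w * 2 / (m - 1)   # RBF width = w x center spacing
  d2_uc <- outer(rowSums(U^2), rowSums(C^2), "+") - 2 * U %*% t(C)
  Phi <- cbind(exp(-d2_uc / (2 * sigma^2)), 1)  # bias column
  n_nodes <- nrow(U)
  n_rbf <- ncol(Phi)

  # initialize W so the latent grid maps onto the first two PCs of X
  sds <- apply(X, 2, sd)
  Tgt <- matrix(0, n_nodes, D)
  Tgt[, 1] <- U[, 1] * sds[1]
  if (D >= 2) Tgt[, 2] <- U[, 2] * sds[2]
  W <- solve(crossprod(Phi) + 1e-8 * diag(n_rbf), crossprod(Phi, Tgt))
  Y <- Phi %*% W
  d2 <- outer(rowSums(Y^2), rowSums(X^2), "+") - 2 * Y %*% t(X)
  beta <- 1 / mean(d2)

  obj_trace <- numeric(0)
  ll_trace <- numeric(0)
  converged <- FALSE
  R <- NULL
  for (it in seq_len(max_iter)) {
    # E-step
    A <- -beta / 2 * d2
    amax <- apply(A, 2, max)
    Ez <- exp(sweep(A, 2, amax))
    col_sum <- colSums(Ez)
    ll <- sum(amax + log(col_sum)) +
      N * (D / 2 * log(beta / (2 * pi)) - log(n_nodes))
    obj <- ll - l / 2 * sum(W^2)
    if (length(obj_trace) &&
        obj < obj_trace[length(obj_trace)] - 1e-9 * (1 + abs(obj)))
      stop("internal error: EM objective decreased")
    obj_trace <- c(obj_trace, obj)
    ll_trace <- c(ll_trace, ll)
    R <- sweep(Ez, 2, col_sum, "/")
    if (length(obj_trace) > 1) {
      rel <- abs(diff(tail(obj_trace, 2))) / (1 + abs(obj))
      if (rel < tol) { converged <- TRUE; break }
    }
    # M-step: mapping weights (penalized LS), then noise precision
    G <- rowSums(R)
    W <- solve(crossprod(Phi, G * Phi) + (l / beta) * diag(n_rbf),
               crossprod(Phi, R %*% X))
    Y <- Phi %*% W
    d2 <- outer(rowSums(Y^2), rowSums(X^2), "+") - 2 * Y %*% t(X)
    beta <- N * D / sum(R * d2)
  }
  structure(list(U = U, Phi = Phi, W = W, beta = beta, R = R, X = X,
                 loglik = obj_trace, loglik_data = ll_trace, D = D, k = k,
                 m = m, sigma = sigma, l = l, n_iter = length(obj_trace),
                 converged = converged, set_ids = rownames(K), seed = seed),
            class = "kgtm")
}

#' @export
print.kgtm <- function(x, ...) {
  cat(sprintf(
    "kernel GTM: %d sets, D = %d, %dx%d latent grid, %dx%d RBFs, %d EM iterations%s\n",
    ncol(x$R), x$D, x$k, x$k, x$m, x$m, x$n_iter,
    if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Project gene-sets onto the 2D map
#'
#' Posterior-mean latent coordinates: each set's responsibilities over the
#' latent grid weight the node positions, so coordinates are convex
#' combinations of grid nodes and lie in `[-1, 1]^2`.  Identical inputs
#' receive identical coordinates.
#'
#' @param model fitted [kgtm_fit()] object.
#' @param set_ids optional ids for the output rows.
#' @param neglog10p optional color values (association in -log10(p) units).
#' @return data frame set_id, x, y and (when given) neglog10p.
#' @export
kgtm_project <- function(model, set_ids = NULL, neglog10p = NULL) {
  coords <- t(model$R) %*% model$U
  out <- data.frame(
    set_id = set_ids %||% model$set_ids %||% sprintf("set%03d", seq_len(nrow(coords))),
    x = coords[, 1], y = coords[, 2], stringsAsFactors = FALSE)
  if (!is.null(neglog10p)) out$neglog10p <- neglog10p
  rownames(out) <- NULL
  out
}

#' Select the top gene-sets by competitive p-value
#'
#' The `n` smallest competitive p-values (default 50, the usual map size);
#' ties are broken by lexicographic set id.  When fewer than `n` results
#' exist, all are returned with a warning.
#'
#' @param set_results data frame with set_id and p_competitive.
#' @param n number of sets to keep.
#' @return subset of `set_results`.
#' @export
select_top_sets <- function(set_results, n = 50) {
  ord <- order(set_results$p_competitive, set_results$set_id)
  if (nrow(set_results) < n) {
    warning("fewer than ", n, " sets available; returning all")
    return(set_results[ord, , drop = FALSE])
  }
  set_results[ord[seq_len(n)], , drop = FALSE]
}
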