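test_that("Tanimoto similarity counts intersection over union", {
  sets <- list(a = c("g1", "g2", "g3"), b = c("g2", "g3", "g4"),
               c = c("g1", "g2", "g3"), d = c("g8", "g9"))
  K <- tanimoto_matrix(sets)
  expect_equal(K["a", "b"], 0.5)
  expect_equal(K["a", "c"], 1)
  expect_equal(K["a", "d"], 0)
  expect_true(isSymmetric(K))
  expect_equal(diag(K), setNames(rep(1, 4), names(sets)))
  expect_error(tanimoto_matrix(list(a = "g1", bad = character(0))), "bad")
})

test_that("feature dimension follows the centered kernel spectrum", {
  dup <- matrix(1, 5, 5)
  expect_warning(expect_equal(feature_dim(dup), 1L), "zero variance")
  expect_equal(feature_dim(diag(10)), 9L)  # centering removes one dimension
  # two tight clusters: one dominant direction carries almost all variance
  sets <- c(lapply(1:5, function(i) c(sprintf("a%02d", 1:20),
                                      sprintf("x%d", i))),
            lapply(1:5, function(i) c(sprintf("b%02d", 1:20),
                                      sprintf("y%d", i))))
  names(sets) <- sprintf("s%02d", 1:10)
  K <- tanimoto_matrix(sets)
  H <- diag(10) - 1 / 10
  ev <- eigen(H %*% K %*% H, symmetric = TRUE, only.values = TRUE)$values
  pos <- ev[ev > 1e-10]
  d_oracle <- which(cumsum(pos) >= 0.995 * sum(pos))[1]
  expect_equal(feature_dim(K), d_oracle)
  expect_lte(feature_dim(K, 0.5), 2)
})

test_that("latent and RBF grid sizes follow the square-root rules", {
  cfg <- synth_config(seed = 43, n_genes = 300, n_pathways = 16,
                      n_pathway_clusters = 2, pathway_size = 20)
  pw <- gen_pathway_collection(cfg, gen_gwas(cfg)$genes)
  K <- tanimoto_matrix(pw)
  m <- kgtm_fit(K, seed = 1)
  expect_equal(m$k, 4)          # round(sqrt(16))
  expect_equal(m$m, 2)          # round(sqrt(4))
  expect_equal(nrow(m$U), 16)
  expect_equal(dim(m$R), c(16, 16))
  expect_equal(colSums(m$R), rep(1, 16), tolerance = 1e-12)
  expect_error(kgtm_fit(K[1:3, 1:3]), "at least 4")
})

test_that("EM objective is non-decreasing and the fit is reproducible", {
  cfg <- synth_config(seed = 47, n_genes = 300, n_pathways = 25,
                      n_pathway_clusters = 3, pathway_size = 20)
  K <- tanimoto_matrix(gen_pathway_collection(cfg, gen_gwas(cfg)$genes))
  m1 <- kgtm_fit(K, seed = 2)
  m2 <- kgtm_fit(K, seed = 2)
  expect_identical(m1$W, m2$W)
  expect_true(all(diff(m1$loglik) >= -1e-9 * (1 + abs(m1$loglik[-1]))))
})

test_that("kernel-PCA embedding reproduces Tanimoto distances", {
  cfg <- synth_config(seed = 53, n_genes = 400, n_pathways = 20,
                      n_pathway_clusters = 4, pathway_size = 25)
  K <- tanimoto_matrix(gen_pathway_collection(cfg, gen_gwas(cfg)$genes))
  m <- kgtm_fit(K, seed = 1)
  X <- m$X
  D2 <- as.matrix(dist(X))^2
  ref <- outer(diag(K), diag(K), "+") - 2 * K
  off <- upper.tri(ref) & ref > 1e-8
  rel_err <- abs(D2[off] - ref[off]) / ref[off]
  expect_lt(max(rel_err), 0.05)
})

test_that("projection is a convex combination of grid nodes", {
  cfg <- synth_config(seed = 59, n_genes = 300, n_pathways = 16,
                      n_pathway_clusters = 2, pathway_size = 20)
  pw <- gen_pathway_collection(cfg, gen_gwas(cfg)$genes)
  # add exact duplicates of the first pathway
  pw2 <- c(pw, list(dup1 = pw[[1]], dup2 = pw[[1]]))
  K <- tanimoto_matrix(pw2)
  m <- kgtm_fit(K, seed = 1)
  proj <- kgtm_project(m)
  expect_true(all(proj$x >= -1 & proj$x <= 1 & proj$y >= -1 & proj$y <= 1))
  i0 <- which(proj$set_id == names(pw2)[1])
  i1 <- which(proj$set_id == "dup1")
  i2 <- which(proj$set_id == "dup2")
  expect_equal(proj[i1, c("x", "y")], proj[i0, c("x", "y")],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(proj[i2, c("x", "y")], proj[i0, c("x", "y")],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("map order is equivariant under input permutation", {
  cfg <- synth_config(seed = 61, n_genes = 300, n_pathways = 18,
                      n_pathway_clusters = 3, pathway_size = 20)
  pw <- gen_pathway_collection(cfg, gen_gwas(cfg)$genes)
  K <- tanimoto_matrix(pw)
  perm <- sample(length(pw))
  p1 <- kgtm_project(kgtm_fit(K, seed = 1))
  p2 <- kgtm_project(kgtm_fit(K[perm, perm], seed = 1))
  m1 <- as.matrix(p1[match(p2$set_id, p1$set_id), c("x", "y")])
  m2 <- as.matrix(p2[, c("x", "y")])
  # the map has no intrinsic orientation: compare pairwise distances
  expect_equal(as.matrix(dist(m2)), as.matrix(dist(m1)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("planted pathway clusters separate on the fitted map", {
  cfg <- synth_config(seed = 67, n_genes = 500, n_pathways = 24,
                      n_pathway_clusters = 3, pathway_size = 25,
                      pathway_perturb = 0.1)
  pw <- gen_pathway_collection(cfg, gen_gwas(cfg)$genes)
  lab <- attr(pw, "cluster")
  m <- kgtm_fit(tanimoto_matrix(pw), seed = 1)
  proj <- kgtm_project(m)
  D <- as.matrix(dist(cbind(proj$x, proj$y)))
  same <- outer(lab, lab, "==") & upper.tri(D)
  diff_cl <- outer(lab, lab, "!=") & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[diff_cl]))
})

test_that("top-set selection keeps the n smallest p with lexicographic ties", {
  sr <- data.frame(set_id = sprintf("s%02d", 1:60),
                   p_competitive = rep(seq(0.01, 0.59, by = 0.01)[1:30],
                                       each = 2))
  top <- select_top_sets(sr, 50)
  expect_equal(nrow(top), 50)
  expect_true(all(sort(top$p_competitive) == top$p_competitive[order(top$p_competitive)]))
  tie_p <- sr$p_competitive[order(sr$p_competitive)][50]
  at_tie <- sr$set_id[sr$p_competitive == tie_p]
  expect_true(min(at_tie) %in% top$set_id)
  expect_warning(select_top_sets(sr[1:30, ], 50), "fewer")
})

test_that("kriging honors data, handles constants and bounds IDW fields", {
  # data points placed on grid nodes of a 21-point axis
  proj <- data.frame(x = c(-0.5, 0, 0.5, -0.5, 0.5),
                     y = c(-0.5, 0, 0.5, 0.5, -0.5),
                     neglog10p = c(1, 2, 3, 2.5, 1.5))
  s <- krige_surface(proj, grid_resolution = 21)
  gx <- s$grid_x
  for (i in seq_len(nrow(proj))) {
    xi <- which.min(abs(gx - proj$x[i]))
    yi <- which.min(abs(gx - proj$y[i]))
    expect_equal(s$surface[xi, yi], proj$neglog10p[i], tolerance = 0.05)
  }
  const <- krige_surface(data.frame(x = c(0, 0.5, -0.5), y = c(0, 0.5, 0.1),
                                    value = rep(2.2, 3)), 11)
  expect_equal(const$method, "constant")
  expect_true(all(const$surface == 2.2))
  expect_error(krige_surface(proj[1:2, ]), "3 distinct")
})
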