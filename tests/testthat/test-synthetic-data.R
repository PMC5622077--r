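test_that("generators are byte-deterministic under a fixed seed", {
  cfg <- synth_config(seed = 11, n_genes = 120, n_drugs = 100, n_classes = 10,
                      n_pathways = 12, n_pathway_clusters = 3)
  a <- gen_gwas(cfg)
  b <- gen_gwas(cfg)
  expect_identical(a, b)
  la <- gen_drug_library(cfg, a$causal_genes, a$genes)
  lb <- gen_drug_library(cfg, a$causal_genes, a$genes)
  expect_identical(la, lb)
  expect_identical(gen_pathway_collection(cfg, a$genes),
                   gen_pathway_collection(cfg, a$genes))
  expect_identical(gen_ppi(a$genes, cfg), gen_ppi(a$genes, cfg))
})

test_that("config validation rejects impossible settings", {
  expect_error(synth_config(n_genes = 0), "count")
  expect_error(synth_config(planted_bias = 1.5), "planted_bias")
  expect_error(synth_config(ld_rho = 1), "ld_rho")
  expect_error(synth_config(n_genes = 10, set_size_range = c(5, 20)),
               "set_size_range")
  expect_error(synth_config(n_drugs = 50, n_classes = 10), "10 drugs")
})

test_that("gene layout spans several chromosomes without overlaps", {
  cfg <- synth_config(seed = 3, n_genes = 250)
  g <- gen_gwas(cfg)$genes
  expect_gte(length(unique(g$chrom)), 2)
  for (ch in unique(g$chrom)) {
    gg <- g[g$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1)
      expect_true(all(gg$start[-1] > gg$end[-nrow(gg)]))
  }
  expect_true(all(g$start <= g$end))
})

test_that("null configuration yields uniform SNP p-values", {
  cfg <- synth_config(seed = 5, n_genes = 1000, snps_per_gene = 10,
                      ld_rho = 0, effect_delta = 0)
  snps <- gen_gwas(cfg)$snps
  expect_equal(nrow(snps), 10000)
  ks <- suppressWarnings(ks.test(snps$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("within-gene Z correlation tracks the LD parameter", {
  cfg <- synth_config(seed = 9, n_genes = 500, snps_per_gene = 10,
                      ld_rho = 0.9, effect_delta = 0)
  z <- matrix(gen_gwas(cfg)$snps$z, nrow = 500, ncol = 10, byrow = TRUE)
  C <- cor(z)
  mean_off <- mean(C[upper.tri(C)])
  expect_lt(abs(mean_off - 0.9), 0.05)
})

test_that("planted signal strength is monotone in effect size", {
  med_causal_p <- vapply(c(0, 1, 2.5), function(delta) {
    cfg <- synth_config(seed = 21, n_genes = 300, effect_delta = delta)
    g <- gen_gwas(cfg)
    median(g$snps$p[g$snps$gene_id %in% g$causal_genes])
  }, numeric(1))
  expect_true(all(diff(med_causal_p) < 0))
})

test_that("drug library respects class sizes, bias boundaries and set sizes", {
  cfg <- synth_config(seed = 13, n_genes = 400, n_drugs = 120, n_classes = 10,
                      planted_bias = 1, causal_gene_fraction = 0.2,
                      set_size_range = c(5, 15))
  g <- gen_gwas(cfg)
  lib <- gen_drug_library(cfg, g$causal_genes, g$genes)
  sizes <- lengths(lib$drug_sets)
  expect_true(all(sizes >= 5 & sizes <= 15))
  expect_true(all(table(substr(lib$atc_map$atc_code, 1, 3)) >= 10))
  expect_true(all(names(lib$drug_sets) %in% lib$atc_map$drug_id))
  planted <- lib$atc_map$drug_id[lib$atc_map$atc_code == "N05A"]
  for (d in planted)
    expect_true(all(lib$drug_sets[[d]] %in% g$causal_genes))
  expect_error(gen_drug_library(cfg, "NOT_A_GENE", g$genes), "subset")
})

test_that("higher planted bias gives larger overlap with the causal set", {
  mean_overlap <- vapply(c(0.4, 0.8), function(b) {
    cfg <- synth_config(seed = 17, n_genes = 400, n_drugs = 100,
                        n_classes = 10, planted_bias = b)
    g <- gen_gwas(cfg)
    lib <- gen_drug_library(cfg, g$causal_genes, g$genes)
    planted <- lib$atc_map$drug_id[lib$atc_map$atc_code == "N05A"]
    mean(vapply(lib$drug_sets[planted],
                function(s) sum(s %in% g$causal_genes) / length(s),
                numeric(1)))
  }, numeric(1))
  expect_gt(mean_overlap[2], mean_overlap[1])
})

test_that("pathway clusters are tighter within than between", {
  cfg <- synth_config(seed = 19, n_genes = 500, n_pathways = 20,
                      n_pathway_clusters = 2, pathway_size = 30,
                      pathway_perturb = 0.1)
  pw <- gen_pathway_collection(cfg, gen_gwas(cfg)$genes)
  K <- tanimoto_matrix(pw)
  lab <- attr(pw, "cluster")
  same <- outer(lab, lab, "==") & upper.tri(K)
  diff_cl <- outer(lab, lab, "!=") & upper.tri(K)
  expect_gt(mean(K[same]), mean(K[diff_cl]))
})

test_that("zero perturbation duplicates the cluster template exactly", {
  cfg <- synth_config(seed = 23, n_genes = 200, n_pathways = 6,
                      n_pathway_clusters = 2, pathway_perturb = 0)
  pw <- gen_pathway_collection(cfg, gen_gwas(cfg)$genes)
  K <- tanimoto_matrix(pw)
  lab <- attr(pw, "cluster")
  expect_true(all(K[outer(lab, lab, "==")] == 1))
})

test_that("a single-pathway collection writes valid GMT", {
  cfg <- synth_config(seed = 29, n_genes = 100, n_pathways = 1,
                      n_pathway_clusters = 1)
  pw <- gen_pathway_collection(cfg, gen_gwas(cfg)$genes)
  expect_length(pw, 1)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(pw, path)
  back <- read_gmt(path)
  expect_identical(unname(lengths(back)), unname(lengths(pw)))
  expect_setequal(back[[1]], pw[[1]])
})

test_that("PPI generator obeys topology, score and hub contracts", {
  cfg <- synth_config(seed = 31, n_genes = 100)
  g3 <- data.frame(gene_id = c("A", "B", "C"))
  full <- gen_ppi(g3, cfg, topology = "full")
  expect_equal(nrow(full), 3)
  expect_true(all(full$combined_score >= 0 & full$combined_score <= 1000))
  expect_true(all(full$protein1 != full$protein2))
  genes <- gen_gwas(cfg)$genes[1:40, ]
  hubbed <- gen_ppi(genes, cfg, topology = "hub", hub_gene = genes$gene_id[5],
                    p_edge = 0.05)
  deg <- table(c(hubbed$protein1, hubbed$protein2))
  expect_equal(names(which.max(deg)), genes$gene_id[5])
})

test_that("synthetic bundle round-trips through the package readers", {
  cfg <- synth_config(seed = 37, n_genes = 60, n_drugs = 100, n_classes = 10,
                      n_pathways = 6, n_pathway_clusters = 2,
                      pathway_size = 15)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_bundle(cfg, dir)
  expect_true(all(file.exists(paths)))
  snps <- read_summary_stats(paths[["snps"]])
  expect_equal(nrow(snps), 600)
  expect_length(read_gmt(paths[["drugs"]]), 100)
})
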