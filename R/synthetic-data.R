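#' Configuration for the synthetic-data generators
#'
#' Bundles and validates every knob of the synthetic study: a GWAS with
#' block-exchangeable LD and a planted set of causal genes, a drug library
#' with one therapeutic class enriched for causal targets, a clustered
#' pathway collection, and a random PPI graph.  The defaults describe the
#' study conditions used throughout the package's own validation: 2000 genes
#' with 10 SNPs each, within-gene LD 0.2, 5% causal genes with a +2 shift on
#' the causal SNP Z-scores, 300 drugs in 10 ATC classes (30 each, so every
#' class clears the minimum class size of 10), and a planted class that
#' samples 90% of its target genes from the causal set.
#'
#' @param seed integer seed; the same config always reproduces byte-identical
#'   outputs.
#' @param n_genes number of genes.
#' @param snps_per_gene SNPs per gene.
#' @param ld_rho exchangeable within-gene correlation of SNP Z-scores, in
#'   `[0, 1)`.
#' @param causal_gene_fraction fraction of genes carrying signal.
#' @param effect_delta mean shift added to every SNP Z-score in a causal gene.
#' @param n_drugs number of drugs; must be at least `10 * n_classes`.
#' @param set_size_range integer `c(min, max)` genes per drug.
#' @param n_classes number of ATC classes.
#' @param planted_class ATC code of the class enriched for causal genes.
#' @param planted_bias probability that a planted-class drug samples a member
#'   gene from the causal set.
#' @param n_pathways number of pathways in the synthetic collection.
#' @param n_pathway_clusters number of pathway clusters.
#' @param pathway_size genes per pathway template.
#' @param pathway_perturb fraction of template genes swapped out per pathway.
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(seed = 1L,
                         n_genes = 2000L,
                         snps_per_gene = 10L,
                         ld_rho = 0.2,
                         causal_gene_fraction = 0.05,
                         effect_delta = 2,
                         n_drugs = 300L,
                         set_size_range = c(5L, 30L),
                         n_classes = 10L,
                         planted_class = "N05A",
                         planted_bias = 0.9,
                         n_pathways = 60L,
                         n_pathway_clusters = 4L,
                         pathway_size = 30L,
                         pathway_perturb = 0.1) {
  counts <- c(n_genes = n_genes, snps_per_gene = snps_per_gene,
              n_drugs = n_drugs, n_classes = n_classes,
              n_pathways = n_pathways, n_pathway_clusters = n_pathway_clusters,
              pathway_size = pathway_size)
  if (any(!is.finite(counts)) || any(counts < 1))
    stop("configuration error: counts must be positive integers")
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed) ||
      abs(seed) >= 2^31 - 16)
    stop("configuration error: seed must be a single 32-bit integer")
  if (ld_rho < 0 || ld_rho >= 1)
    stop("configuration error: ld_rho must be in [0, 1)")
  if (planted_bias < 0 || planted_bias > 1)
    stop("configuration error: planted_bias must be in [0, 1]")
  if (causal_gene_fraction <= 0 || causal_gene_fraction > 1)
    stop("configuration error: causal_gene_fraction must be in (0, 1]")
  if (length(set_size_range) != 2 || set_size_range[1] < 1 ||
      set_size_range[1] > set_size_range[2])
    stop("configuration error: set_size_range must be c(min, max), min >= 1")
  if (set_size_range[2] > n_genes)
    stop("configuration error: set_size_range max exceeds n_genes")
  if (n_drugs < 10 * n_classes)
    stop("configuration error: n_drugs must allow >= 10 drugs per class")
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    snps_per_gene = as.integer(snps_per_gene), ld_rho = ld_rho,
    causal_gene_fraction = causal_gene_fraction, effect_delta = effect_delta,
    n_drugs = as.integer(n_drugs),
    set_size_range = as.integer(set_size_range),
    n_classes = as.integer(n_classes), planted_class = planted_class,
    planted_bias = planted_bias, n_pathways = as.integer(n_pathways),
    n_pathway_clusters = as.integer(n_pathway_clusters),
    pathway_size = as.integer(pathway_size),
    pathway_perturb = pathway_perturb
  ), class = "synth_config")
}

check_config <- function(config) {
  if (!inherits(config, "synth_config"))
    stop("configuration error: expected a synth_config object")
  config
}

#' Generate synthetic GWAS summary statistics with planted causal genes
#'
#' Genes are laid out on at least two chromosomes with non-overlapping
#' 20 kb bodies spaced 200 kb apart (so the default 35 kb / 10 kb scoring
#' windows never bridge neighbours).  Within each gene the SNP Z-scores are
#' multivariate normal with exchangeable correlation `ld_rho`; SNPs in causal
#' genes get mean `effect_delta`, all others mean 0.  Two-sided p-values are
#' emitted and MAFs are drawn uniform on `[0.005, 0.5]` so the standard 1%
#' MAF filter always has work to do.
#'
#' @param config a [synth_config()].
#' @return list with `snps` (snp_id, chrom, pos, z, p, maf, gene_id),
#'   `genes` (gene_id, chrom, start, end, strand), `causal_genes`
#'   (character), and `ld` (named list of per-gene SNP correlation matrices,
#'   dimnames = SNP ids).
#' @export
gen_gwas <- function(config) {
  config <- check_config(config)
  n <- config$n_genes
  s <- config$snps_per_gene
  withr::with_seed(config$seed, {
    n_chrom <- min(22L, max(2L, ceiling(n / 100)))
    chrom <- as.character(rep_len(seq_len(n_chrom), n))
    idx <- ave(seq_len(n), chrom, FUN = seq_along)
    start <- 1e6 + (idx - 1) * 2e5
    len <- round(runif(n, 5000, 50000))  # varied so size covariates inform
    end <- start + len - 1
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gene_id <- sprintf("G%05d", seq_len(n))
    genes <- data.frame(gene_id = gene_id, chrom = chrom,
                        start = as.integer(start), end = as.integer(end),
                        strand = strand, stringsAsFactors = FALSE)

    n_causal <- max(1L, round(config$causal_gene_fraction * n))
    causal <- sort(sample(gene_id, n_causal))

    rho <- config$ld_rho
    shared <- rnorm(n)
    eps <- matrix(rnorm(n * s), n, s)
    mu <- ifelse(gene_id %in% causal, config$effect_delta, 0)
    z <- mu + sqrt(rho) * shared + sqrt(1 - rho) * eps  # rows = genes
    zv <- as.vector(t(z))
    offsets <- if (s == 1) matrix(round(len / 2), n, 1) else
      t(vapply(len, function(L) round(seq(100, L - 100, length.out = s)),
               numeric(s)))
    pos <- as.integer(t(start + offsets))
    snps <- data.frame(
      snp_id = sprintf("rs%07d", seq_len(n * s)),
      chrom = rep(chrom, each = s),
      pos = pos,
      z = zv,
      p = 2 * pnorm(-abs(zv)),
      maf = runif(n * s, 0.005, 0.5),
      gene_id = rep(gene_id, each = s),
      stringsAsFactors = FALSE
    )
    R <- matrix(rho, s, s)
    diag(R) <- 1
    ld <- lapply(seq_len(n), function(i) {
      Ri <- R
      ids <- snps$snp_id[((i - 1) * s + 1):(i * s)]
      dimnames(Ri) <- list(ids, ids)
      Ri
    })
    names(ld) <- gene_id
    list(snps = snps, genes = genes, causal_genes = causal, ld = ld)
  })
}

#' Generate a synthetic drug library with one planted therapeutic class
#'
#' Drugs are assigned round-robin to `n_classes` ATC codes, so every class
#' holds at least 10 drugs by construction.  A drug in the planted class
#' draws `Binomial(size, planted_bias)` of its member genes from the causal
#' set and the remainder uniformly from the remaining genes; drugs in other
#' classes sample uniformly from all genes.
#'
#' @param config a [synth_config()].
#' @param causal_genes character vector of causal gene ids (subset of
#'   `gene_table$gene_id`).
#' @param gene_table gene table as produced by [gen_gwas()].
#' @return list with `drug_sets` (named list drug_id -> gene ids) and
#'   `atc_map` (data frame drug_id, atc_code).
#' @export
gen_drug_library <- function(config, causal_genes, gene_table) {
  config <- check_config(config)
  all_genes <- gene_table$gene_id
  if (!all(causal_genes %in% all_genes))
    stop("causal_genes must be a subset of gene_table$gene_id")
  if (config$set_size_range[2] > length(all_genes))
    stop("set_size_range max exceeds number of genes")
  withr::with_seed(config$seed + 1L, {
    codes <- c(config$planted_class,
               sprintf("B%02dA", seq_len(config$n_classes - 1)))
    drug_id <- sprintf("D%04d", seq_len(config$n_drugs))
    drug_class <- rep_len(codes, config$n_drugs)
    sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                    config$n_drugs, replace = TRUE)
    drug_sets <- vector("list", config$n_drugs)
    for (i in seq_len(config$n_drugs)) {
      size <- sizes[i]
      if (drug_class[i] == config$planted_class) {
        nc <- min(rbinom(1, size, config$planted_bias), length(causal_genes))
        members <- if (nc > 0) sample(causal_genes, nc) else character(0)
        rest <- setdiff(all_genes, members)
        members <- c(members, sample(rest, size - nc))
      } else {
        members <- sample(all_genes, size)
      }
      drug_sets[[i]] <- sort(members)
    }
    names(drug_sets) <- drug_id
    list(drug_sets = drug_sets,
         atc_map = data.frame(drug_id = drug_id, atc_code = drug_class,
                              stringsAsFactors = FALSE))
  })
}

#' Generate a clustered synthetic pathway collection
#'
#' Each cluster starts from a random template of `pathway_size` genes;
#' member pathways swap a fraction `pathway_perturb` of the template for
#' random outside genes, so within-cluster Tanimoto similarity exceeds
#' between-cluster similarity in expectation.
#'
#' @param config a [synth_config()].
#' @param gene_table gene table as produced by [gen_gwas()].
#' @return named list of pathways (character vectors of gene ids) with a
#'   `cluster` attribute giving the true cluster label of each pathway.
#' @export
gen_pathway_collection <- function(config, gene_table) {
  config <- check_config(config)
  all_genes <- gene_table$gene_id
  if (config$pathway_size > length(all_genes))
    stop("configuration error: pathway_size exceeds number of genes")
  withr::with_seed(config$seed + 2L, {
    k <- config$n_pathway_clusters
    per <- diff(c(round(seq(0, config$n_pathways, length.out = k + 1))))
    n_swap <- round(config$pathway_perturb * config$pathway_size)
    sets <- list()
    labels <- integer(0)
    for (cl in seq_len(k)) {
      template <- sample(all_genes, config$pathway_size)
      for (j in seq_len(per[cl])) {
        members <- template
        if (n_swap > 0) {
          out <- sample(config$pathway_size, n_swap)
          members[out] <- sample(setdiff(all_genes, template), n_swap)
        }
        sets[[sprintf("PWY_C%d_S%02d", cl, j)]] <- sort(members)
        labels <- c(labels, cl)
      }
    }
    attr(sets, "cluster") <- labels
    sets
  })
}

#' Generate a synthetic STRING-style PPI edge table
#'
#' Undirected weighted edges with combined scores in `[0, 1000]` (the STRING
#' convention), no self-loops, deterministic under the config seed.
#'
#' @param gene_table gene table (only `gene_id` is used).
#' @param config a [synth_config()].
#' @param topology `"random"` (Erdos-Renyi with edge probability `p_edge`),
#'   `"full"` (every pair connected), or `"hub"` (the hub gene connected to
#'   everything, remaining pairs random).
#' @param p_edge edge probability for the random part.
#' @param hub_gene gene id used as hub when `topology = "hub"` (defaults to
#'   the first gene).
#' @return data frame with columns protein1, protein2, combined_score.
#' @export
gen_ppi <- function(gene_table, config, topology = c("random", "full", "hub"),
                    p_edge = 0.1, hub_gene = NULL) {
  config <- check_config(config)
  topology <- match.arg(topology)
  ids <- gene_table$gene_id
  if (length(ids) < 2) stop("need at least 2 genes")
  withr::with_seed(config$seed + 3L, {
    pairs <- t(utils::combn(ids, 2))
    keep <- switch(topology,
      full = rep(TRUE, nrow(pairs)),
      random = runif(nrow(pairs)) < p_edge,
      hub = {
        hub <- hub_gene %||% ids[1]
        is_hub <- pairs[, 1] == hub | pairs[, 2] == hub
        is_hub | runif(nrow(pairs)) < p_edge
      })
    pairs <- pairs[keep, , drop = FALSE]
    data.frame(protein1 = pairs[, 1], protein2 = pairs[, 2],
               combined_score = sample(150:999, nrow(pairs), replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

#' Write a full synthetic input bundle to disk
#'
#' Emits the plain-text files the readers in this package (and the field's
#' usual tools) consume: summary-stats TSV, gene BED-like TSV, GMT files for
#' drugs and pathways, an ATC map TSV and a STRING-style edge TSV.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if missing).
#' @return named character vector of paths, invisibly.
#' @export
write_synthetic_bundle <- function(config, dir) {
  config <- check_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gwas <- gen_gwas(config)
  lib <- gen_drug_library(config, gwas$causal_genes, gwas$genes)
  pathways <- gen_pathway_collection(config, gwas$genes)
  ppi <- gen_ppi(gwas$genes, config)
  paths <- c(
    snps = file.path(dir, "summary_stats.tsv"),
    genes = file.path(dir, "genes.tsv"),
    drugs = file.path(dir, "drug_sets.gmt"),
    atc = file.path(dir, "atc_map.tsv"),
    pathways = file.path(dir, "pathways.gmt"),
    ppi = file.path(dir, "ppi_edges.tsv"),
    causal = file.path(dir, "causal_genes.txt")
  )
  write_tsv(gwas$snps[c("snp_id", "chrom", "pos", "p", "maf")], paths["snps"])
  write_tsv(gwas$genes, paths["genes"])
  write_gmt(lib$drug_sets, paths["drugs"])
  write_tsv(lib$atc_map, paths["atc"])
  write_gmt(pathways, paths["pathways"])
  write_tsv(ppi, paths["ppi"])
  writeLines(gwas$causal_genes, paths["causal"])
  invisible(paths)
}
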