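#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()]: synthetic-data
#' settings (see [synth_config()]), analysis thresholds, and stage toggles.
#' Any subset may be overridden via the `config` argument of
#' [run_pipeline()] or a YAML file with the same structure.
#'
#' @param seed master seed; all stage seeds derive from it and are recorded
#'   in the run report.
#' @param out_dir output directory for the run.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("gwas2drug_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    synth = list(),                # overrides for synth_config()
    maf_threshold = 0.01,
    ld_intercept = 1,
    window_up = 35000,
    window_down = 10000,
    exclude = NULL,                # optional genomic_region() to drop
    mc_draws = 500,
    alpha = 0.05,
    min_class_size = 10,
    atc_level = 3,
    top_n = 50,
    variance_fraction = 0.995,
    stages = list(synth = TRUE, prep = TRUE, genescore = TRUE,
                  setscan = TRUE, enrich = TRUE, maps = FALSE,
                  networks = FALSE)
  )
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  base <- default_config(seed = config$seed %||% 1L,
                         out_dir = config$out_dir %||% tempfile("gwas2drug_run_"))
  modifyList(base, config)
}

require_stage <- function(stages, stage, needed) {
  on <- vapply(needed, function(s) isTRUE(stages[[s]]), logical(1))
  if (!all(on))
    stop("stage '", stage, "' requires stage(s): ",
         paste(needed[!on], collapse = ", "))
}

#' Run the full GWAS-to-drug-repurposing workflow
#'
#' Executes the enabled stages in dependency order on a synthetic input
#' bundle: data generation, summary-statistic preparation (MAF filter,
#' inflation correction, optional region exclusion, SNP-to-gene
#' assignment), gene scoring, competitive drug-set scan, ATC class
#' enrichment, and optionally pathway maps and PPI network metrics.  All
#' outputs are written as TSV under `out_dir` and are byte-identical across
#' reruns of the same config.
#'
#' @param config a configuration list (see [default_config()]) or the path
#'   to a YAML file holding one; partial configs are completed with
#'   defaults.
#' @return the run report (named list of per-stage counts, seeds and output
#'   paths), invisibly; also written to `out_dir/report.yaml`.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- read_run_config(if (is.character(config)) config else config)
  stages <- cfg$stages
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed, out_dir = cfg$out_dir)
  fail <- function(stage, msg) stop("stage '", stage, "' failed: ", msg)

  if (!isTRUE(stages$synth)) fail("synth", "pipeline requires the synth stage")
  scfg <- do.call(synth_config, c(list(seed = cfg$seed), cfg$synth))
  gwas <- gen_gwas(scfg)
  lib <- gen_drug_library(scfg, gwas$causal_genes, gwas$genes)
  pathways <- gen_pathway_collection(scfg, gwas$genes)
  report$synth <- list(n_snps = nrow(gwas$snps), n_genes = nrow(gwas$genes),
                       n_causal = length(gwas$causal_genes),
                       n_drugs = length(lib$drug_sets),
                       n_pathways = length(pathways))

  if (isTRUE(stages$prep)) {
    snps <- filter_maf(gwas$snps, cfg$maf_threshold)
    snps <- correct_inflation(snps, cfg$ld_intercept)
    genes <- gwas$genes
    if (!is.null(cfg$exclude))
      genes <- exclude_region(genes, cfg$exclude, cfg$window_up,
                              cfg$window_down)
    assignment <- map_snps_to_genes(snps, genes, cfg$window_up,
                                    cfg$window_down)
    write_tsv(snps[c("snp_id", "chrom", "pos", "p", "maf")],
              file.path(cfg$out_dir, "snps_prepared.tsv"))
    report$prep <- list(n_snps_kept = nrow(snps),
                        n_genes_kept = nrow(genes),
                        n_assignments = nrow(assignment))
  }

  if (isTRUE(stages$genescore)) {
    require_stage(stages, "genescore", "prep")
    gene_results <- score_genes(snps, assignment, ld = gwas$ld,
                                mc_draws = cfg$mc_draws, seed = cfg$seed)
    write_tsv(gene_results, file.path(cfg$out_dir, "gene_results.tsv"))
    report$genescore <- list(n_genes_scored = nrow(gene_results))
  }

  if (isTRUE(stages$setscan)) {
    require_stage(stages, "setscan", c("prep", "genescore"))
    covs <- gene_covariates(gene_results, genes, snps, assignment)
    set_results <- competitive_scan(gene_results, lib$drug_sets, covs)
    write_tsv(set_results, file.path(cfg$out_dir, "drug_set_results.tsv"))
    report$setscan <- list(
      n_sets_tested = nrow(set_results),
      n_sig_bonf = sum(set_results$p_bonf <= cfg$alpha),
      n_sig_bh = sum(set_results$q_bh <= cfg$alpha),
      n_sig_by = sum(set_results$q_by <= cfg$alpha))
  }

  if (isTRUE(stages$enrich)) {
    require_stage(stages, "enrich", "setscan")
    classes <- build_atc_classes(lib$drug_sets, lib$atc_map,
                                 cfg$min_class_size, cfg$atc_level)
    enrich <- class_enrichment_scan(set_results, classes, cfg$alpha)
    write_tsv(enrich, file.path(cfg$out_dir, "class_enrichment.tsv"))
    report$enrich <- list(n_classes_scanned = attr(enrich, "n_scanned"),
                          n_classes_significant = sum(enrich$significant),
                          top_class = enrich$class_code[1],
                          top_class_auc = enrich$auc[1])
  }

  if (isTRUE(stages$maps)) {
    require_stage(stages, "maps", "setscan")
    pw_results <- competitive_scan(gene_results, pathways, covs)
    top <- select_top_sets(pw_results, cfg$top_n)
    K <- tanimoto_matrix(pathways[top$set_id])
    model <- kgtm_fit(K, seed = cfg$seed,
                      variance_fraction = cfg$variance_fraction)
    proj <- kgtm_project(model, top$set_id,
                         -log10(pmax(top$p_competitive, 1e-300)))
    write_tsv(proj, file.path(cfg$out_dir, "pathway_projection.tsv"))
    surf <- krige_surface(proj, grid_resolution = 50)
    write_tsv(as.data.frame(surf$surface),
              file.path(cfg$out_dir, "pathway_surface.tsv"))
    report$maps <- list(n_mapped = nrow(proj), kgtm_iters = model$n_iter,
                        surface_method = surf$method)
  }

  if (isTRUE(stages$networks)) {
    require_stage(stages, "networks", "genescore")
    edges <- gen_ppi(gwas$genes, scfg)
    g <- ppi_graph(edges)
    metrics <- node_metrics(g)
    write_tsv(metrics, file.path(cfg$out_dir, "node_metrics.tsv"))
    report$networks <- list(n_nodes = igraph::vcount(g),
                            n_edges = igraph::ecount(g))
  }

  yaml::write_yaml(report, file.path(cfg$out_dir, "report.yaml"))
  invisible(report)
}
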