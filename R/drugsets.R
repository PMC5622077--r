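#' Build drug gene-sets from interaction tables
#'
#' Merges interaction records of two kinds: curated drug-gene pairs
#' ("dgidb" style, no affinity) and binding-affinity records ("kidb" style,
#' Ki in nM).  Affinity records are kept only when `affinity <= ki_max_nM`
#' (default 10 uM, a standard activity cut-off).  Gene symbols are mapped
#' to stable gene identifiers; symbols without a mapping are dropped and
#' counted in the attached report, and drugs whose sets end up empty are
#' dropped and listed there too.  Output is independent of input row order.
#'
#' @param interactions data frame with columns drug_id, gene_symbol, source
#'   (values containing "kidb" are treated as affinity records) and
#'   optionally affinity_nM.
#' @param symbol_map data frame with columns symbol, gene_id.
#' @param ki_max_nM affinity cut-off in nM for kidb-like records.
#' @return named list drug_id -> sorted gene ids, with attribute `report`
#'   (list: n_unmapped_symbols, unmapped_symbols, dropped_drugs,
#'   n_ki_filtered).
#' @export
build_drug_sets <- function(interactions, symbol_map, ki_max_nM = 10000) {
  x <- interactions
  is_ki <- grepl("kidb", x$source, ignore.case = TRUE)
  aff <- if (!is.null(x$affinity_nM)) x$affinity_nM else rep(NA_real_, nrow(x))
  if (any(!is.na(aff) & aff <= 0)) stop("affinities must be positive")
  keep <- !is_ki | (!is.na(aff) & aff <= ki_max_nM)
  n_ki_filtered <- sum(!keep)
  x <- x[keep, , drop = FALSE]
  gid <- symbol_map$gene_id[match(x$gene_symbol, symbol_map$symbol)]
  unmapped <- sort(unique(x$gene_symbol[is.na(gid)]))
  x <- x[!is.na(gid), , drop = FALSE]
  gid <- gid[!is.na(gid)]
  sets <- lapply(split(gid, x$drug_id), function(g) sort(unique(g)))
  all_drugs <- sort(unique(interactions$drug_id))
  dropped <- setdiff(all_drugs, names(sets))
  sets <- sets[order(names(sets))]
  attr(sets, "report") <- list(
    n_unmapped_symbols = length(unmapped), unmapped_symbols = unmapped,
    dropped_drugs = dropped, n_ki_filtered = n_ki_filtered)
  sets
}

#' Group drugs into ATC classes of a minimum size
#'
#' ATC codes are truncated to `level` characters (default 3, e.g. "N05");
#' drugs carrying several codes appear in every matching class; classes
#' with fewer than `min_class_size` drugs are excluded from scanning.
#'
#' @param drug_sets named list of drug gene-sets (only the names are used).
#' @param atc_map data frame with columns drug_id, atc_code (possibly
#'   several rows per drug).
#' @param min_class_size smallest class retained (default 10).
#' @param level number of leading ATC characters defining a class.
#' @return named list class code -> drug ids.
#' @export
build_atc_classes <- function(drug_sets, atc_map, min_class_size = 10,
                              level = 3) {
  x <- atc_map[atc_map$drug_id %in% names(drug_sets), , drop = FALSE]
  code <- substr(x$atc_code, 1, level)
  classes <- lapply(split(x$drug_id, code), function(d) sort(unique(d)))
  classes <- classes[vapply(classes, length, 0L) >= min_class_size]
  classes[order(names(classes))]
}

#' Select and partition significant druggable genes
#'
#' Restricts to genes with a druggability tier, removes genes whose padded
#' window intersects the excluded region (the MHC by default), keeps those
#' passing the druggable-genome threshold, and partitions them by which of
#' the two Bonferroni thresholds they pass ("protein_coding" for the
#' genome-wide cut, "druggable_only" otherwise) and by tier.
#'
#' @param gene_results output of [score_genes()] (uses `p_combined`).
#' @param tiers data frame with columns gene_id, tier (values
#'   1/2/3A/3B).
#' @param thresholds list from [druggable_thresholds()].
#' @param genes gene table (needed for the region exclusion).
#' @param region excluded [genomic_region()]; default [mhc_region()].
#' @param window_up,window_down padding used for the exclusion.
#' @return data frame gene_id, p, tier, category sorted by p.
#' @export
select_significant_druggable <- function(gene_results, tiers, thresholds,
                                         genes, region = mhc_region(),
                                         window_up = 35000,
                                         window_down = 10000) {
  kept_genes <- exclude_region(genes, region, window_up, window_down)
  x <- gene_results[gene_results$gene_id %in% tiers$gene_id &
                      gene_results$gene_id %in% kept_genes$gene_id, ,
                    drop = FALSE]
  x <- x[x$p_combined <= thresholds$t_druggable, , drop = FALSE]
  out <- data.frame(
    gene_id = x$gene_id, p = x$p_combined,
    tier = tiers$tier[match(x$gene_id, tiers$gene_id)],
    category = ifelse(x$p_combined <= thresholds$t_genomewide,
                      "protein_coding", "druggable_only"),
    stringsAsFactors = FALSE)
  out[order(out$p, out$gene_id), , drop = FALSE]
}
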