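#' Build an undirected PPI graph from a STRING-style edge table
#'
#' Edges below `min_score` are dropped, self-loops removed, and duplicate
#' edges collapsed to their maximum combined score.
#'
#' @param edges data frame with columns protein1, protein2, combined_score
#'   in `[0, 1000]`.
#' @param min_score minimum combined score for edge inclusion.
#' @param nodes optional character vector of vertices to include even when
#'   isolated.
#' @return an igraph object with edge attribute `combined_score`.
#' @export
ppi_graph <- function(edges, min_score = 0, nodes = NULL) {
  e <- edges[edges$combined_score >= min_score &
               edges$protein1 != edges$protein2, , drop = FALSE]
  verts <- unique(c(nodes, e$protein1, e$protein2))
  g <- igraph::graph_from_data_frame(
    e[, c("protein1", "protein2", "combined_score")],
    directed = FALSE, vertices = data.frame(name = verts))
  igraph::simplify(g, edge.attr.comb = list(combined_score = "max"))
}

#' Normalized degree and betweenness centrality per gene
#'
#' Degree is normalized by the number of possible neighbours
#' (`100 * deg / (n - 1)`), betweenness by the number of vertex pairs a
#' node could separate (`100 * 2B / ((n - 1)(n - 2))`), both on the
#' unweighted topology; the interaction score only gates edge inclusion.
#' Hub flags mark genes above configurable percentage thresholds.
#'
#' @param graph igraph object or edge data frame (see [ppi_graph()]).
#' @param min_score drop edges below this combined score first.
#' @param hub_degree,hub_betweenness percentage thresholds for the hub
#'   flags (defaults 5% and 2.5%).
#' @return data frame gene_id, degree, degree_norm, betweenness_norm,
#'   hub_degree, hub_betweenness.
#' @export
node_metrics <- function(graph, min_score = 0, hub_degree = 5,
                         hub_betweenness = 2.5) {
  g <- if (igraph::is_igraph(graph)) {
    igraph::delete_edges(
      graph, igraph::E(graph)[igraph::E(graph)$combined_score < min_score])
  } else ppi_graph(graph, min_score)
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph")
  deg <- igraph::degree(g)
  deg_norm <- if (n > 1) 100 * deg / (n - 1) else rep(0, n)
  if (n < 3) {
    warning("fewer than 3 nodes: betweenness reported as 0")
    btw_norm <- rep(0, n)
  } else {
    btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
    btw_norm <- 100 * btw / ((n - 1) * (n - 2) / 2)
  }
  data.frame(gene_id = igraph::V(g)$name, degree = unname(deg),
             degree_norm = unname(deg_norm),
             betweenness_norm = unname(btw_norm),
             hub_degree = unname(deg_norm > hub_degree),
             hub_betweenness = unname(btw_norm > hub_betweenness),
             stringsAsFactors = FALSE)
}

#' Fruchterman-Reingold layout, deterministic under a seed
#'
#' @param graph igraph object.
#' @param seed RNG seed.
#' @param iterations number of layout iterations.
#' @return matrix of 2D positions (one row per vertex, rownames = gene
#'   ids); a single vertex is placed at the origin.
#' @export
layout_fr <- function(graph, seed = 1, iterations = 200) {
  n <- igraph::vcount(graph)
  if (n == 0) stop("empty graph")
  if (n == 1) {
    pos <- matrix(0, 1, 2)
    rownames(pos) <- igraph::V(graph)$name
    return(pos)
  }
  pos <- withr::with_seed(seed,
    igraph::layout_with_fr(graph, niter = iterations))
  rownames(pos) <- igraph::V(graph)$name
  pos
}

#' Subnetwork of proteins targeted by several drugs of a class
#'
#' Induced subgraph on the genes targeted by at least `min_drugs` distinct
#' drugs of the class (the display rule used for class target networks).
#'
#' @param graph igraph PPI graph.
#' @param drug_sets_in_class named list of gene-sets for the drugs in the
#'   class.
#' @param min_drugs minimum number of distinct targeting drugs.
#' @return induced igraph subgraph (possibly empty, with a warning).
#' @export
class_target_subgraph <- function(graph, drug_sets_in_class, min_drugs = 2) {
  if (length(drug_sets_in_class) == 0) stop("class has no drugs")
  counts <- table(unlist(lapply(drug_sets_in_class, unique)))
  keep <- names(counts)[counts >= min_drugs]
  keep <- intersect(keep, igraph::V(graph)$name)
  if (length(keep) == 0)
    warning("no gene targeted by >= ", min_drugs, " drugs; empty subgraph")
  igraph::induced_subgraph(graph, keep)
}

#' Subnetwork of genes recurring across many pathways
#'
#' Induced subgraph on the genes present in at least `min_pathways` sets of
#' a pathway collection (the display rule used for pathway core networks).
#'
#' @param graph igraph PPI graph.
#' @param pathway_sets named list of pathway gene-sets.
#' @param min_pathways minimum number of containing pathways.
#' @return induced igraph subgraph (possibly empty, with a warning).
#' @export
pathway_core_subgraph <- function(graph, pathway_sets, min_pathways = 10) {
  if (length(pathway_sets) == 0) stop("empty pathway collection")
  counts <- table(unlist(lapply(pathway_sets, unique)))
  keep <- names(counts)[counts >= min_pathways]
  keep <- intersect(keep, igraph::V(graph)$name)
  if (length(keep) == 0)
    warning("no gene in >= ", min_pathways, " pathways; empty subgraph")
  igraph::induced_subgraph(graph, keep)
}

#' Classify significant genes against GWAS loci
#'
#' Each gene gets exactly one label: `overlap` when its strand-aware
#' 35 kb / 10 kb padded body intersects a locus, else `ld_window` when the
#' symmetric 500 kb padded body does, else `independent`.
#'
#' @param genes gene table (gene_id, chrom, start, end, strand).
#' @param loci data frame of loci (chrom, start, end; 1-based inclusive).
#' @param near `c(upstream, downstream)` padding for the overlap label
#'   (strand-aware).
#' @param ld_window `c(left, right)` symmetric padding for the LD label.
#' @return data frame gene_id, category (factor with the three levels).
#' @export
classify_genes_vs_loci <- function(genes, loci, near = c(35000, 10000),
                                   ld_window = c(500000, 500000)) {
  if (any(loci$start > loci$end)) stop("invalid loci: start > end")
  near_pad <- padded_interval(genes, near[1], near[2])
  gch <- norm_chrom(genes$chrom)
  lch <- norm_chrom(loci$chrom)
  hits_any <- function(lo, hi) {
    vapply(seq_len(nrow(genes)), function(i) {
      any(lch == gch[i] & loci$start <= hi[i] & loci$end >= lo[i])
    }, logical(1))
  }
  overlap <- hits_any(near_pad$lo, near_pad$hi)
  ld <- hits_any(pmax(1, genes$start - ld_window[1]),
                 genes$end + ld_window[2])
  category <- ifelse(overlap, "overlap",
                     ifelse(ld, "ld_window", "independent"))
  data.frame(gene_id = genes$gene_id,
             category = factor(category,
                               levels = c("overlap", "ld_window",
                                          "independent")),
             stringsAsFactors = FALSE)
}
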