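#' Read GWAS summary statistics from a TSV file
#'
#' Coordinates are 1-based inclusive.  Required columns (after applying
#' `col_map`) are the SNP id, chromosome, position and p-value; a minor
#' allele frequency column is used when present.  Extra columns are ignored.
#' Malformed rows (non-positive positions, p outside (0, 1], MAF outside
#' (0, 0.5]) abort with the offending file line numbers.
#'
#' @param path TSV file with a header row.
#' @param col_map named character vector mapping canonical names
#'   (`snp`, `chrom`, `pos`, `p`, `maf`) to the column names in the file.
#' @return data frame with columns snp_id, chrom, pos, p and (if available)
#'   maf.
#' @export
read_summary_stats <- function(path,
                               col_map = c(snp = "snp_id", chrom = "chrom",
                                           pos = "pos", p = "p", maf = "maf")) {
  x <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  required <- c("snp", "chrom", "pos", "p")
  missing <- required[!col_map[required] %in% names(x)]
  if (length(missing))
    stop("format error: missing required column(s): ",
         paste(col_map[missing], collapse = ", "))
  out <- data.frame(
    snp_id = as.character(x[[col_map[["snp"]]]]),
    chrom = as.character(x[[col_map[["chrom"]]]]),
    pos = as.integer(x[[col_map[["pos"]]]]),
    p = as.numeric(x[[col_map[["p"]]]]),
    stringsAsFactors = FALSE
  )
  has_maf <- !is.na(col_map["maf"]) && col_map[["maf"]] %in% names(x)
  if (has_maf) out$maf <- as.numeric(x[[col_map[["maf"]]]])
  bad <- !is.finite(out$pos) | out$pos < 1 |
    !is.finite(out$p) | out$p <= 0 | out$p > 1
  if (has_maf) bad <- bad | !is.finite(out$maf) | out$maf <= 0 | out$maf > 0.5
  if (any(bad)) {
    # +1 for the header: report file line numbers, not record indices
    lines <- which(bad) + 1L
    stop("validation error: malformed row(s) at file line(s) ",
         paste(head(lines, 20), collapse = ", "),
         if (sum(bad) > 20) " ..." else "")
  }
  out
}

#' Filter SNPs on minor allele frequency
#'
#' Keeps records with `maf >= threshold` (the conventional 1% cut-off is
#' inclusive).  Row order is preserved; the filter is idempotent.
#'
#' @param snps summary-statistics data frame with a `maf` column.
#' @param threshold MAF threshold in (0, 0.5].
#' @return filtered data frame.
#' @export
filter_maf <- function(snps, threshold = 0.01) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 0.5)
    stop("threshold must be in (0, 0.5]")
  if (is.null(snps$maf)) stop("snps has no 'maf' column")
  snps[!is.na(snps$maf) & snps$maf >= threshold, , drop = FALSE]
}

#' Correct summary statistics with an LD-score regression intercept
#'
#' Each p-value is converted to a 1-df chi-square statistic, divided by the
#' intercept, and converted back; the p-value ranking is preserved and with
#' intercept > 1 no p-value ever decreases.  Intercepts below 1 are clamped
#' to 1 with a warning (no deflation is applied).
#'
#' @param snps summary-statistics data frame with a `p` column.
#' @param intercept LD-score regression intercept (> 0).
#' @return data frame with corrected `p`.
#' @export
correct_inflation <- function(snps, intercept) {
  if (!is.numeric(intercept) || length(intercept) != 1 || intercept <= 0)
    stop("intercept must be a single positive number")
  if (intercept < 1) {
    warning("intercept < 1 clamped to 1; no deflation applied")
    intercept <- 1
  }
  chi <- qchisq(snps$p, df = 1, lower.tail = FALSE)
  snps$p <- pchisq(chi / intercept, df = 1, lower.tail = FALSE)
  snps
}

#' Restrict several studies to their shared SNPs
#'
#' Used when comparing studies of increasing sample size: every study is
#' restricted to the SNP ids present in all of them, preserving each
#' study's own row order.
#'
#' @param studies list (length >= 2) of summary-statistics data frames.
#' @return list of data frames over the common SNP id set.
#' @export
intersect_studies <- function(studies) {
  if (length(studies) < 2) stop("need at least 2 studies")
  shared <- Reduce(intersect, lapply(studies, function(s) s$snp_id))
  if (length(shared) == 0) warning("empty SNP intersection across studies")
  lapply(studies, function(s) s[s$snp_id %in% shared, , drop = FALSE])
}

#' A genomic region (1-based inclusive coordinates)
#' @param chrom chromosome label ("6" and "chr6" are equivalent).
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return list with chrom, start, end.
#' @export
genomic_region <- function(chrom, start, end) {
  if (start > end) stop("start must be <= end")
  list(chrom = norm_chrom(chrom), start = as.numeric(start),
       end = as.numeric(end))
}

#' The extended MHC region conventionally excluded from schizophrenia
#' gene-level analyses (chr6:25652464-33771788, extreme LD).
#' @return a [genomic_region()].
#' @export
mhc_region <- function() genomic_region("6", 25652464, 33771788)

# Strand-aware padded interval: upstream extends 5' of the transcription
# start, downstream 3' of the end; on the minus strand the genomic roles of
# the two windows swap.
padded_interval <- function(genes, window_up, window_down) {
  minus <- genes$strand == "-"
  lo <- ifelse(minus, genes$start - window_down, genes$start - window_up)
  hi <- ifelse(minus, genes$end + window_up, genes$end + window_down)
  data.frame(lo = pmax(1, lo), hi = hi)
}

#' Drop genes whose padded window intersects a region
#'
#' Applies the same strand-aware 35 kb upstream / 10 kb downstream padding
#' used for SNP-to-gene assignment before testing the overlap, so genes
#' scored from SNPs inside the region are also removed.
#'
#' @param genes gene table (gene_id, chrom, start, end, strand).
#' @param region a [genomic_region()], e.g. [mhc_region()].
#' @param window_up,window_down padding in bp.
#' @return filtered gene table.
#' @export
exclude_region <- function(genes, region, window_up = 35000,
                           window_down = 10000) {
  pad <- padded_interval(genes, window_up, window_down)
  hit <- norm_chrom(genes$chrom) == region$chrom &
    pad$lo <= region$end & pad$hi >= region$start
  genes[!hit, , drop = FALSE]
}

#' Assign SNPs to genes with strand-aware windows
#'
#' A SNP is assigned to every gene whose padded window contains it; the
#' default window is 35 kb upstream (5' of the transcription start) and
#' 10 kb downstream, chosen to capture regulatory regions.  A SNP may map
#' to several genes.
#'
#' @param snps summary-statistics data frame (snp_id, chrom, pos).
#' @param genes gene table (gene_id, chrom, start, end, strand).
#' @param window_up,window_down window sizes in bp (>= 0).
#' @return data frame with columns snp_id, gene_id.
#' @export
map_snps_to_genes <- function(snps, genes, window_up = 35000,
                              window_down = 10000) {
  if (window_up < 0 || window_down < 0) stop("windows must be >= 0")
  if (nrow(snps) == 0 || nrow(genes) == 0)
    return(data.frame(snp_id = character(0), gene_id = character(0)))
  pad <- padded_interval(genes, window_up, window_down)
  gr_genes <- GenomicRanges::GRanges(
    norm_chrom(genes$chrom), IRanges::IRanges(pad$lo, pad$hi))
  gr_snps <- GenomicRanges::GRanges(
    norm_chrom(snps$chrom), IRanges::IRanges(snps$pos, snps$pos))
  hits <- GenomicRanges::findOverlaps(gr_snps, gr_genes)
  data.frame(snp_id = snps$snp_id[S4Vectors::queryHits(hits)],
             gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}
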