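#' Enrichment curve over a ranked list of gene-sets
#'
#' Gene-sets are ranked by score (association in -log10(p) units,
#' descending); walking down the ranking, the curve tracks the fraction of
#' hits recovered (y) against the fraction of non-hits passed (x), from
#' (0, 0) to (1, 1).  Tied scores are processed as a block contributing a
#' single diagonal segment, so the trapezoidal area equals the normalized
#' Wilcoxon-Mann-Whitney U statistic with half credit for ties.
#'
#' @param scores numeric scores (larger = stronger association).
#' @param hits logical vector flagging the gene-sets in the class of
#'   interest; at least one hit and one non-hit required.
#' @return data frame of curve points (x, y).
#' @export
enrichment_curve <- function(scores, hits) {
  hits <- as.logical(hits)
  n1 <- sum(hits)
  n0 <- sum(!hits)
  if (n1 == 0) stop("zero hits: enrichment curve undefined")
  if (n0 == 0) stop("zero non-hits: enrichment curve undefined")
  blocks <- score_blocks(scores, hits)
  data.frame(x = c(0, cumsum(blocks$n_nonhit)) / n0,
             y = c(0, cumsum(blocks$n_hit)) / n1)
}

# hit / non-hit counts per tied-score block, strongest block first
score_blocks <- function(scores, hits) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  h <- hits[ord]
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  n_hit <- vapply(seq_along(ends),
                  function(b) sum(h[starts[b]:ends[b]]), numeric(1))
  list(n_hit = n_hit, n_nonhit = r$lengths - n_hit)
}

#' Area under the enrichment curve, in percent
#'
#' Trapezoidal area under [enrichment_curve()] times 100.  Equals
#' `100 * U / (n1 * n0)` where U is the Wilcoxon-Mann-Whitney statistic with
#' ties credited 0.5: 50% is the random expectation, 100% perfect
#' enrichment.  Invariant to strictly monotone transforms of the scores.
#'
#' @inheritParams enrichment_curve
#' @return AUC percentage in `[0, 100]`.
#' @export
enrichment_auc <- function(scores, hits) {
  hits <- as.logical(hits)
  n1 <- sum(hits)
  n0 <- sum(!hits)
  if (n1 == 0 || n0 == 0) stop("need at least one hit and one non-hit")
  blocks <- score_blocks(scores, hits)
  # trapezoid accumulated in integer units of hit x non-hit pairs, so
  # boundary cases (perfect separation) come out exact
  cumh <- 0
  area2 <- 0
  for (b in seq_along(blocks$n_hit)) {
    area2 <- area2 + blocks$n_nonhit[b] * (2 * cumh + blocks$n_hit[b])
    cumh <- cumh + blocks$n_hit[b]
  }
  100 * (area2 / 2) / (n1 * n0)
}

#' One-sided Wilcoxon-Mann-Whitney p-value for class enrichment
#'
#' Tests whether the hit scores are stochastically larger than the non-hit
#' scores.  Exact enumeration when the pooled sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections.  A completely tied sample carries no evidence
#' and returns 1.
#'
#' @param hit_scores,nonhit_scores numeric score vectors (both non-empty).
#' @param alternative "greater" (hits score higher, default), "less", or
#'   "two.sided".
#' @return p-value.
#' @export
wmw_pvalue <- function(hit_scores, nonhit_scores, alternative = "greater") {
  if (length(hit_scores) == 0 || length(nonhit_scores) == 0)
    stop("both groups must be non-empty")
  pooled <- c(hit_scores, nonhit_scores)
  if (length(unique(pooled)) == 1) return(1)
  exact <- length(pooled) <= 20 && !anyDuplicated(pooled)
  suppressWarnings(
    wilcox.test(hit_scores, nonhit_scores, alternative = alternative,
                exact = exact, correct = TRUE)$p.value)
}

#' Scan ATC drug classes for enrichment in competitive results
#'
#' For every class, ranks all scored drugs by -log10(competitive p),
#' computes the enrichment AUC and its one-sided Wilcoxon-Mann-Whitney
#' p-value, and applies a Bonferroni correction over the number of classes
#' actually scanned (e.g. 49 classes give a threshold of about 1e-3 at
#' alpha = 0.05).  Classes with no scored drug are skipped with a warning.
#'
#' @param set_results competitive results data frame (set_id,
#'   p_competitive), one row per drug.
#' @param classes named list class code -> drug ids, e.g. from
#'   [build_atc_classes()].
#' @param alpha familywise error rate for the significance flag.
#' @return data frame class_code, n_hits, n_nonhits, auc, u_statistic,
#'   p_wmw, p_bonf, significant; attribute `n_scanned` holds the Bonferroni
#'   denominator.
#' @export
class_enrichment_scan <- function(set_results, classes, alpha = 0.05) {
  score <- -log10(pmax(set_results$p_competitive, 1e-300))
  rows <- lapply(names(classes), function(code) {
    hits <- set_results$set_id %in% classes[[code]]
    if (!any(hits)) return(NULL)
    if (all(hits)) return(NULL)
    data.frame(class_code = code, n_hits = sum(hits),
               n_nonhits = sum(!hits),
               auc = enrichment_auc(score, hits),
               p_wmw = wmw_pvalue(score[hits], score[!hits]),
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0)
    warning(skipped, " class(es) skipped (no scored drugs, or all of them)")
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no scannable classes")
  n_scanned <- nrow(out)
  out$u_statistic <- out$auc / 100 * out$n_hits * out$n_nonhits
  out$p_bonf <- pmin(1, out$p_wmw * n_scanned)
  out$significant <- out$p_wmw <= alpha / n_scanned
  out <- out[order(out$p_wmw, out$class_code), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_scanned") <- n_scanned
  out
}
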