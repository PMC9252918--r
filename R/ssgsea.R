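#' Single-sample gene-set enrichment score
#'
#' Computes, per sample, the running-sum enrichment statistic of a gene
#' set against the sample's expression ranking (Barbie-style ssGSEA):
#' genes are sorted in descending order of their (z-scored) expression,
#' set members accumulate weight proportional to |value|^exponent and
#' non-members accumulate the uniform empirical CDF, and the score is the
#' sum over all rank positions of the difference between the two
#' cumulative distributions. With \code{exponent = 0} the score is purely
#' rank-based and invariant to any monotone transform of the values.
#' Ties are broken by a stable sort on (-value, gene id).
#'
#' @param z genes x samples matrix, typically from
#'   [zscore_across_samples()].
#' @param genes character vector of set members (or a single-element
#'   named list).
#' @param exponent weighting exponent on |value| for set members
#'   (default 0.25).
#' @param normalize divide the score by the number of genes for
#'   cross-set comparability (default FALSE: raw running-sum score).
#' @return named numeric vector, one score per sample.
#' @export
ssgsea_score <- function(z, genes, exponent = 0.25, normalize = FALSE) {
  if (is.list(genes)) genes <- unlist(genes, use.names = FALSE)
  all_genes <- rownames(z)
  in_set <- all_genes %in% genes
  if (!any(in_set)) {
    stop("no gene of the set is present in the expression matrix")
  }
  if (all(in_set)) {
    stop("gene set covers every gene in the matrix (empty complement)")
  }
  G <- length(all_genes)
  n_out <- sum(!in_set)
  scores <- vapply(seq_len(ncol(z)), function(j) {
    v <- z[, j]
    ord <- order(-v, all_genes)  # stable: descending value, then gene id
    inr <- in_set[ord]
    w <- abs(v[ord])^exponent
    w[!inr] <- 0
    wsum <- sum(w)
    p_in <- if (wsum == 0) cumsum(inr) / sum(inr) else cumsum(w) / wsum
    p_out <- cumsum(!inr) / n_out
    sum(p_in - p_out)
  }, numeric(1))
  names(scores) <- colnames(z)
  if (normalize) scores <- scores / G
  scores
}

#' ssGSEA scores for a collection of gene sets
#'
#' @param z genes x samples z-scored matrix.
#' @param sets named list of gene sets.
#' @param ... passed to [ssgsea_score()].
#' @return sets x samples matrix of scores.
#' @export
ssgsea_matrix <- function(z, sets, ...) {
  t(vapply(sets, function(s) ssgsea_score(z, s, ...),
           numeric(ncol(z))))
}
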