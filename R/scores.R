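#' Proliferation index
#'
#' An 11-gene expression score of proliferative activity: the per-sample
#' aggregate (sum by default) of z-scored log2(TPM + 1) values of the
#' proliferation panel genes. A sample at the cohort mean for every panel
#' gene scores 0. At least \code{min_genes} of the panel genes must be
#' present in the matrix.
#'
#' @param m genes x samples TPM matrix.
#' @param pi_genes the proliferation gene panel (default: the shipped
#'   11-gene reconstructed panel).
#' @param aggregate "sum" (default; the index is on the sum scale) or
#'   "mean".
#' @param min_genes minimum panel genes required (default 8).
#' @return named numeric vector of PI values per sample, with the genes
#'   used in the \code{genes_used} attribute.
#' @export
proliferation_index <- function(m, pi_genes = builtin_panels("PI_11"),
                                aggregate = c("sum", "mean"),
                                min_genes = 8L) {
  aggregate <- match.arg(aggregate)
  present <- intersect(pi_genes, rownames(m))
  if (length(present) < min_genes) {
    stop("too few proliferation genes present (",
         length(present), " of ", length(pi_genes), "); missing: ",
         paste(setdiff(pi_genes, rownames(m)), collapse = ", "))
  }
  z <- zscore_across_samples(m, log_transform = TRUE)
  vals <- z[present, , drop = FALSE]
  pi <- if (aggregate == "sum") colSums(vals) else colMeans(vals)
  attr(pi, "genes_used") <- present
  attr(pi, "aggregate") <- aggregate
  pi
}

#' Classify a paired proliferation-index change
#'
#' Change classes on the PI delta (late - early): "high_increase" when
#' delta > 1, "increase" when 0.4 < delta <= 1, "decrease" when
#' delta < -0.4, otherwise "no_change". The four classes partition the
#' real line.
#'
#' @param early,late PI values (vectorized).
#' @return data.frame with \code{early}, \code{late}, \code{delta},
#'   \code{class} (factor).
#' @export
classify_pi_change <- function(early, late) {
  delta <- late - early
  cls <- ifelse(delta > 1, "high_increase",
                ifelse(delta > 0.4, "increase",
                       ifelse(delta < -0.4, "decrease", "no_change")))
  data.frame(early = early, late = late, delta = delta,
             class = factor(cls, levels = c("decrease", "no_change",
                                            "increase", "high_increase")))
}

#' Count expressed cancer germline antigens
#'
#' A CGA is counted expressed in a sample when its TPM is strictly
#' greater than the threshold (default 2). Operates on the TPM-scale
#' matrix, not a z-scored one.
#'
#' @param m genes x samples TPM matrix.
#' @param cga_genes CGA panel (default: the shipped reconstructed panel
#'   of 27 hematological CGAs).
#' @param tpm_threshold strict expression threshold (default 2).
#' @return named integer vector of counts per sample.
#' @export
count_expressed_cgas <- function(m, cga_genes = builtin_panels("CGA_27"),
                                 tpm_threshold = 2) {
  present <- intersect(cga_genes, rownames(m))
  if (length(present) == 0L) {
    return(stats::setNames(integer(ncol(m)), colnames(m)))
  }
  counts <- colSums(m[present, , drop = FALSE] > tpm_threshold)
  stats::setNames(as.integer(counts), colnames(m))
}

#' Classify a paired CGA-count change
#'
#' "increased" when the late count exceeds the early count by at least
#' \code{min_delta} (default 3, the increase rule used for CGA
#' expression); a symmetric "decreased" class at -\code{min_delta} makes
#' the classifier partition the integers; otherwise "no_change".
#'
#' @param early,late CGA counts (vectorized).
#' @param min_delta count change defining an increase (default 3).
#' @return data.frame with \code{early}, \code{late}, \code{delta},
#'   \code{class}.
#' @export
classify_cga_change <- function(early, late, min_delta = 3L) {
  delta <- late - early
  cls <- ifelse(delta >= min_delta, "increased",
                ifelse(delta <= -min_delta, "decreased", "no_change"))
  data.frame(early = early, late = late, delta = delta,
             class = factor(cls, levels = c("decreased", "no_change",
                                            "increased")))
}

#' Gene-panel index
#'
#' The per-sample mean of z-scored log2(TPM + 1) values over a gene
#' panel; used for the NFkB index, HLA class I/II scores and similar
#' panel summaries.
#'
#' @param m genes x samples TPM matrix.
#' @param panel character vector of panel genes.
#' @return named numeric vector per sample.
#' @export
panel_index <- function(m, panel) {
  present <- intersect(panel, rownames(m))
  if (length(present) == 0L) {
    stop("no panel gene present in the expression matrix")
  }
  z <- zscore_across_samples(m, log_transform = TRUE)
  colMeans(z[present, , drop = FALSE])
}

#' Paired fold change of a gene's expression
#'
#' FC = (TPM_late + c) / (TPM_early + c) with pseudocount c, plus the
#' threshold flags used for MYC-transcription reporting (FC > 1.5 and
#' FC > 3).
#'
#' @param m genes x samples TPM matrix.
#' @param gene gene id.
#' @param early,late sample ids.
#' @param pseudocount c (default 1).
#' @return list with \code{fc}, \code{fc_gt_1_5}, \code{fc_gt_3}.
#' @export
fold_change <- function(m, gene, early, late, pseudocount = 1) {
  if (!gene %in% rownames(m)) stop("gene not in matrix: ", gene)
  missing <- setdiff(c(early, late), colnames(m))
  if (length(missing)) stop("sample(s) not in matrix: ",
                            paste(missing, collapse = ", "))
  fc <- (m[gene, late] + pseudocount) / (m[gene, early] + pseudocount)
  list(fc = unname(fc), fc_gt_1_5 = unname(fc > 1.5),
       fc_gt_3 = unname(fc > 3))
}

#' Spearman correlations across a score table
#'
#' Computes Spearman rho and p for each requested pair of score columns,
#' adds Benjamini-Hochberg adjusted p-values, and flags correlations at
#' or above the 0.45 highlight convention. Pairs with fewer than
#' \code{min_overlap} complete observations are skipped with a warning.
#'
#' @param scores data.frame or matrix, samples x scores.
#' @param pairs list of length-2 character vectors of score names; by
#'   default all distinct pairs.
#' @param min_overlap minimum complete observations per pair (default 5).
#' @param highlight rho threshold for the highlight flag (default 0.45).
#' @return data.frame with \code{score_a}, \code{score_b}, \code{rho},
#'   \code{p_value}, \code{p_adj}, \code{n}, \code{highlighted}.
#' @export
spearman_panel <- function(scores, pairs = NULL, min_overlap = 5L,
                           highlight = 0.45) {
  scores <- as.data.frame(scores)
  if (is.null(pairs)) {
    nm <- colnames(scores)
    idx <- utils::combn(nm, 2, simplify = FALSE)
    pairs <- idx
  }
  rows <- lapply(pairs, function(pr) {
    a <- scores[[pr[1]]]
    b <- scores[[pr[2]]]
    ok <- stats::complete.cases(a, b)
    if (sum(ok) < min_overlap) {
      warning("skipping pair ", pr[1], " / ", pr[2],
              ": only ", sum(ok), " overlapping samples")
      return(NULL)
    }
    ct <- suppressWarnings(
      stats::cor.test(a[ok], b[ok], method = "spearman"))
    data.frame(score_a = pr[1], score_b = pr[2],
               rho = unname(ct$estimate), p_value = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(score_a = character(), score_b = character(),
                      rho = numeric(), p_value = numeric(),
                      p_adj = numeric(), n = integer(),
                      highlighted = logical()))
  }
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$highlighted <- out$rho >= highlight
  out
}
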