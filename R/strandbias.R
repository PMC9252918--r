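#' Transcriptional strand-bias test for the melphalan signature contexts
#'
#' Compares transcribed versus untranscribed counts of C>T mutations in a
#' set of trinucleotide contexts (by default CCA, GCA, GCC, GCG, GCT, the
#' contexts characteristic of the melphalan signature). Under no bias the
#' two strands accumulate mutations at equal rates, so conditional on the
#' total the transcribed count is Binomial(n, 1/2); the test is the
#' two-sided exact binomial test (minimum-likelihood summation, as in
#' \code{stats::binom.test}), which is the exact conditional equivalent of
#' a two-rate Poisson comparison.
#'
#' @param sc a \code{stranded_counts} object from [stranded_counts()].
#' @param contexts raw trinucleotides restricting the C>T channels tested.
#' @param alpha significance level (default 0.05).
#' @return a \code{strand_bias_result} list with
#'   \code{transcribed_count}, \code{untranscribed_count}, \code{ratio}
#'   (transcribed/untranscribed, \code{NA} when undefined),
#'   \code{p_value}, \code{significant}, and \code{defined} (FALSE when
#'   both counts are zero).
#' @export
strand_bias_test <- function(sc,
                             contexts = c("CCA", "GCA", "GCC", "GCG", "GCT"),
                             alpha = 0.05) {
  ch <- mm1_channels(contexts)
  missing <- setdiff(ch, rownames(sc))
  if (length(missing)) stop("unknown channels: ", paste(missing, collapse = ", "))
  tr <- sum(sc[ch, "transcribed"])
  un <- sum(sc[ch, "untranscribed"])
  n <- tr + un
  if (n == 0L) {
    res <- list(transcribed_count = 0L, untranscribed_count = 0L,
                ratio = NA_real_, p_value = 1, significant = FALSE,
                defined = FALSE, alpha = alpha)
    return(structure(res, class = "strand_bias_result"))
  }
  p <- stats::binom.test(tr, n, p = 0.5, alternative = "two.sided")$p.value
  res <- list(
    transcribed_count = as.integer(tr),
    untranscribed_count = as.integer(un),
    ratio = if (un == 0L) Inf else tr / un,
    p_value = p,
    significant = p < alpha,
    defined = TRUE,
    alpha = alpha)
  structure(res, class = "strand_bias_result")
}

#' @export
print.strand_bias_result <- function(x, ...) {
  cat("Transcriptional strand bias (C>T, melphalan contexts)\n")
  cat("  transcribed:", x$transcribed_count,
      " untranscribed:", x$untranscribed_count,
      " ratio:", format(x$ratio, digits = 3), "\n")
  cat("  exact binomial p =", format(x$p_value, digits = 4),
      if (x$significant) "(significant)" else "(not significant)", "\n")
  if (!x$defined) cat("  [no informative counts]\n")
  invisible(x)
}
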