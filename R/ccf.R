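#' Cancer cell fraction from VAF, purity and local copy number
#'
#' Uses the standard transform: with tumor purity \eqn{\rho}, local tumor
#' total copy number \eqn{CN_t} and normal copy number 2, the expected VAF
#' of a mutation at multiplicity \eqn{m} carried by a fraction CCF of
#' tumor cells is \eqn{VAF = CCF \rho m / (\rho CN_t + (1-\rho) 2)}.
#' Multiplicity is estimated as
#' \code{clamp(round(vaf/purity * (purity*CNt + (1-purity)*2)), 1, max(CNt, 1))}
#' and the CCF solved from the same relation. CCF estimates above
#' \code{cap} (default 1.5) are truncated and flagged as likely
#' multiplicity or copy-number errors.
#'
#' @param vaf variant allele fractions.
#' @param purity tumor purity in (0, 1].
#' @param total_cn local tumor total copy number (recycled).
#' @param cap upper CCF cap.
#' @return data.frame with columns \code{ccf}, \code{multiplicity},
#'   \code{tumor_cn}, \code{capped}.
#' @export
ccf_from_vaf <- function(vaf, purity, total_cn = 2L, cap = 1.5) {
  if (any(purity <= 0 | purity > 1)) stop("purity must lie in (0, 1]")
  n <- max(length(vaf), length(purity), length(total_cn))
  vaf <- rep_len(vaf, n)
  purity <- rep_len(purity, n)
  total_cn <- rep_len(total_cn, n)
  denom <- purity * total_cn + (1 - purity) * 2
  mult <- pmin(pmax(round(vaf / purity * denom), 1L), pmax(total_cn, 1L))
  ccf <- vaf * denom / (purity * mult)
  capped <- ccf > cap
  ccf[capped] <- cap
  data.frame(ccf = ccf, multiplicity = as.integer(mult),
             tumor_cn = as.integer(total_cn), capped = capped)
}

#' Per-mutation CCF estimates with copy-number segment lookup
#'
#' Matches each mutation to its covering allele-specific copy-number
#' segment (1-based inclusive coordinates) and applies [ccf_from_vaf()].
#' Positions not covered by any segment fall back to total copy number 2
#' and are flagged in the \code{cn_fallback} column (with a warning).
#'
#' @param muts mutation data.frame (needs \code{chrom}, \code{pos},
#'   \code{vaf}).
#' @param segments data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{total_cn}, \code{minor_cn} (1-based inclusive), or NULL for a
#'   diploid assumption.
#' @param purity scalar tumor purity for this sample.
#' @param cap upper CCF cap (default 1.5).
#' @return \code{muts} with appended columns \code{ccf},
#'   \code{multiplicity}, \code{tumor_cn}, \code{capped},
#'   \code{cn_fallback}.
#' @export
compute_ccf <- function(muts, segments = NULL, purity, cap = 1.5) {
  if (length(purity) != 1L || purity <= 0 || purity > 1) {
    stop("purity must be a single value in (0, 1]")
  }
  cn <- rep(2L, nrow(muts))
  fallback <- rep(FALSE, nrow(muts))
  if (!is.null(segments) && nrow(segments) > 0L) {
    if (any(segments$start > segments$end)) {
      stop("segment start must be <= end")
    }
    if (any(segments$minor_cn > segments$total_cn)) {
      stop("segment minor_cn must be <= total_cn")
    }
    fallback <- rep(TRUE, nrow(muts))
    for (i in seq_len(nrow(segments))) {
      hit <- muts$chrom == segments$chrom[i] &
        muts$pos >= segments$start[i] & muts$pos <= segments$end[i]
      cn[hit] <- as.integer(segments$total_cn[i])
      fallback[hit] <- FALSE
    }
    if (any(fallback)) {
      warning(sum(fallback),
              " mutation(s) not covered by any segment; assuming CN 2")
    }
  }
  est <- ccf_from_vaf(muts$vaf, purity, cn, cap = cap)
  muts$ccf <- est$ccf
  muts$multiplicity <- est$multiplicity
  muts$tumor_cn <- est$tumor_cn
  muts$capped <- est$capped
  muts$cn_fallback <- fallback
  muts
}

#' Fraction of mutations supported by RNA reads
#'
#' A mutation is counted as expressed when its RNA alternate-read count
#' reaches \code{min_rna_alt}. Records without RNA data are excluded from
#' the denominator; when no record carries RNA data the fraction is
#' undefined and flagged.
#'
#' @param muts mutation data.frame with an \code{rna_alt_reads} column.
#' @param min_rna_alt minimum supporting RNA reads (default 2).
#' @return list with \code{fraction} (NA when undefined),
#'   \code{n_expressed}, \code{n_informative}, \code{defined}, and the
#'   per-variant logical vector \code{expressed} (NA where RNA data are
#'   missing).
#' @export
expressed_fraction <- function(muts, min_rna_alt = 2L) {
  rna <- muts$rna_alt_reads
  if (is.null(rna)) rna <- rep(NA_integer_, nrow(muts))
  informative <- !is.na(rna)
  expressed <- ifelse(informative, rna >= min_rna_alt, NA)
  n_inf <- sum(informative)
  list(
    fraction = if (n_inf == 0L) NA_real_ else
      sum(expressed[informative]) / n_inf,
    n_expressed = sum(expressed[informative]),
    n_informative = n_inf,
    defined = n_inf > 0L,
    expressed = expressed)
}
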