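# Independent oracles used across the suite. Each is written as a naive,
# direct transcription of the definition, deliberately sharing no code
# with the implementation it checks.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

# hand reverse-complement channel oracle: complement each base, reverse
# the context, and emit the pyrimidine-strand label
oracle_channel <- function(ref, alt, ctx) {
  if (ref %in% c("A", "G")) {
    ref2 <- COMP[[ref]]
    alt2 <- COMP[[alt]]
    ctx2 <- paste0(COMP[[substr(ctx, 3, 3)]],
                   COMP[[substr(ctx, 2, 2)]],
                   COMP[[substr(ctx, 1, 1)]])
  } else {
    ref2 <- ref; alt2 <- alt; ctx2 <- ctx
  }
  paste0(substr(ctx2, 1, 1), "[", ref2, ">", alt2, "]",
         substr(ctx2, 3, 3))
}

oracle_revcomp_triplet <- function(ref, alt, ctx) {
  list(ref = COMP[[ref]], alt = COMP[[alt]],
       ctx = paste0(COMP[[substr(ctx, 3, 3)]], COMP[[substr(ctx, 2, 2)]],
                    COMP[[substr(ctx, 1, 1)]]))
}

# two-sided exact binomial p-value by explicit minimum-likelihood tail sum
oracle_binom_p <- function(k, n, p = 0.5) {
  d <- stats::dbinom(0:n, n, p)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# closed-form CCF transform, recomputed step by step
oracle_ccf <- function(vaf, purity, cn) {
  denom <- purity * cn + (1 - purity) * 2
  mult <- round(vaf / purity * denom)
  if (mult < 1) mult <- 1
  if (mult > max(cn, 1)) mult <- max(cn, 1)
  list(multiplicity = mult, ccf = vaf * denom / (purity * mult))
}

# rule-table oracle for the evolution pattern of a set of cluster means
oracle_pattern <- function(early, late, ts = 0.3, tn = 0.25, tm = 0.1) {
  d <- late - early
  shift <- any(d <= -ts) && any(d >= ts)
  swap <- any(early >= tn & late < tm) && any(early < tm & late >= tn)
  if (shift || swap) return("differential")
  emerges <- any(early < tm & late >= tn)
  retained <- any(early >= tn & late >= tn)
  if (emerges && retained) return("linear")
  "stable"
}

# rule oracle for RAS shifts over labeled mutation trajectories
oracle_ras_shift <- function(early, late, labels, ts = 0.3, tn = 0.25,
                             tm = 0.1) {
  falls <- which((late - early <= -ts) | (early >= tn & late < tm))
  rises <- which(late - early >= tn)
  for (f in falls) for (r in rises) {
    if (labels[f] != labels[r]) return(TRUE)
  }
  FALSE
}

# brute-force single-sample enrichment score with an explicit loop
oracle_ssgsea <- function(vals, genes, set, exponent) {
  ord <- order(-vals, genes)
  v <- vals[ord]
  g <- genes[ord]
  inset <- g %in% set
  wsum <- sum(abs(v[inset])^exponent)
  nout <- sum(!inset)
  p_in <- 0; p_out <- 0; score <- 0
  for (i in seq_along(g)) {
    if (inset[i]) p_in <- p_in + abs(v[i])^exponent / wsum
    else p_out <- p_out + 1 / nout
    score <- score + (p_in - p_out)
  }
  unname(score)
}

# union CCF vectors for a simulated pair, as the pipeline builds them
pair_ccfs <- function(p) {
  ce <- compute_ccf(p$muts_early, p$segments, p$purity[["early"]])
  cl <- compute_ccf(p$muts_late, p$segments, p$purity[["late"]])
  ke <- paste(ce$chrom, ce$pos, ce$ref, ce$alt)
  kl <- paste(cl$chrom, cl$pos, cl$ref, cl$alt)
  uk <- union(ke, kl)
  e <- stats::setNames(rep(0, length(uk)), uk)
  l <- e
  e[ke] <- ce$ccf
  l[kl] <- cl$ccf
  list(early = e, late = l)
}
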