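#' Classify the clonal-evolution pattern of a paired sample
#'
#' Maps a paired-timepoint cluster solution to one of the three clonal
#' evolution patterns observed between myeloma timepoints:
#' \describe{
#'   \item{differential}{a shift in clonal dominance — one cluster falls
#'     by at least \code{tau_shift} while another rises by at least
#'     \code{tau_shift}, or a cluster vanishes (early >= \code{tau_new},
#'     late < \code{tau_minor}) while a distinct cluster emerges
#'     (early < \code{tau_minor}, late >= \code{tau_new}).}
#'   \item{linear}{acquisition of novel aberrations on a retained
#'     backbone — a new cluster emerges while at least one ancestral
#'     cluster persists at both timepoints.}
#'   \item{stable}{no or minor changes — every cluster moves by less
#'     than \code{tau_minor}.}
#' }
#' Rule precedence is differential > linear > stable, and stable is the
#' fallback for solutions matching no rule (minor drift below the shift
#' thresholds); the firing rules are returned as evidence.
#'
#' @param sol a \code{ccf_cluster_solution} from [cluster_pair()].
#' @param tau_shift minimum CCF change calling a dominance shift
#'   (default 0.3).
#' @param tau_new minimum late CCF for an emerging cluster
#'   (default 0.25).
#' @param tau_minor CCF changes below this are "minor" (default 0.1).
#' @param patient_id,pair optional labels carried into the call.
#' @return an \code{evolution_call}: list with \code{pattern} (factor
#'   stable/linear/differential), \code{evidence} (character vector of
#'   rule firings), \code{clusters}, and the thresholds used.
#' @export
classify_evolution <- function(sol, tau_shift = 0.3, tau_new = 0.25,
                               tau_minor = 0.1, patient_id = NA_character_,
                               pair = NULL) {
  cl <- sol$clusters
  early <- cl$mean_ccf_early
  late <- cl$mean_ccf_late
  delta <- late - early
  falls <- which(delta <= -tau_shift)
  rises <- which(delta >= tau_shift)
  vanishes <- which(early >= tau_new & late < tau_minor)
  emerges <- which(early < tau_minor & late >= tau_new)
  retained <- which(early >= tau_new & late >= tau_new)
  evidence <- character()
  shift_pair <- length(falls) > 0L && length(rises) > 0L &&
    length(union(falls, rises)) >= 2L
  swap_pair <- length(vanishes) > 0L && length(emerges) > 0L &&
    length(union(vanishes, emerges)) >= 2L
  if (shift_pair) {
    evidence <- c(evidence, sprintf(
      "cluster %d fell by %.2f while cluster %d rose by %.2f (tau_shift=%.2f)",
      falls[1], -delta[falls[1]], rises[rises != falls[1]][1],
      delta[rises[rises != falls[1]][1]], tau_shift))
  }
  if (swap_pair) {
    evidence <- c(evidence, sprintf(
      "cluster %d vanished (%.2f -> %.2f) while cluster %d emerged (%.2f -> %.2f)",
      vanishes[1], early[vanishes[1]], late[vanishes[1]],
      emerges[emerges != vanishes[1]][1],
      early[emerges[emerges != vanishes[1]][1]],
      late[emerges[emerges != vanishes[1]][1]]))
  }
  if (shift_pair || swap_pair) {
    pattern <- "differential"
  } else if (length(emerges) > 0L && length(retained) > 0L) {
    pattern <- "linear"
    evidence <- c(evidence, sprintf(
      "cluster %d emerged (%.2f -> %.2f) on retained cluster %d (%.2f -> %.2f)",
      emerges[1], early[emerges[1]], late[emerges[1]],
      retained[1], early[retained[1]], late[retained[1]]))
  } else if (all(abs(delta) < tau_minor)) {
    pattern <- "stable"
  } else {
    pattern <- "stable"
    evidence <- c(evidence, sprintf(
      "minor drift only (max |delta| = %.2f < tau_shift = %.2f)",
      max(abs(delta)), tau_shift))
  }
  structure(list(
    patient_id = patient_id, pair = pair,
    pattern = factor(pattern,
                     levels = c("stable", "linear", "differential")),
    evidence = evidence, clusters = cl,
    thresholds = c(tau_shift = tau_shift, tau_new = tau_new,
                   tau_minor = tau_minor)),
    class = "evolution_call")
}

#' @export
print.evolution_call <- function(x, ...) {
  cat("Clonal evolution:", as.character(x$pattern),
      if (!is.na(x$patient_id)) paste0("[", x$patient_id, "]"), "\n")
  for (e in x$evidence) cat("  -", e, "\n")
  invisible(x)
}

#' Detect a RAS shift between two timepoints
#'
#' A RAS shift is the replacement of a dominant KRAS/NRAS-mutant clone by
#' a clone carrying a different KRAS/NRAS mutation: some RAS hotspot
#' mutation's CCF falls by at least \code{tau_shift} (or disappears
#' entirely from an appreciable early CCF) while a different RAS mutation
#' rises by at least \code{tau_new} between the same timepoints.
#'
#' @param ras_ccfs data.frame with one row per RAS hotspot mutation:
#'   columns \code{gene} (KRAS/NRAS), \code{protein_change},
#'   \code{ccf_early}, \code{ccf_late}.
#' @param tau_shift minimum CCF fall (default 0.3).
#' @param tau_new minimum CCF rise of the replacing mutation
#'   (default 0.25).
#' @param tau_minor CCF below which a mutation counts as absent
#'   (default 0.1).
#' @return list with \code{shift} (logical) and \code{detail}
#'   (data.frame of falling/rising mutation pairs; empty when no shift).
#' @export
detect_ras_shift <- function(ras_ccfs, tau_shift = 0.3, tau_new = 0.25,
                             tau_minor = 0.1) {
  if (is.null(ras_ccfs) || nrow(ras_ccfs) == 0L) {
    return(list(shift = FALSE,
                detail = data.frame(falling = character(),
                                    rising = character())))
  }
  delta <- ras_ccfs$ccf_late - ras_ccfs$ccf_early
  falls <- which(delta <= -tau_shift |
                   (ras_ccfs$ccf_early >= tau_new &
                      ras_ccfs$ccf_late < tau_minor))
  rises <- which(delta >= tau_new)
  label <- paste(ras_ccfs$gene, ras_ccfs$protein_change)
  pairs <- expand.grid(f = falls, r = rises)
  pairs <- pairs[label[pairs$f] != label[pairs$r], , drop = FALSE]
  detail <- data.frame(falling = label[pairs$f], rising = label[pairs$r],
                       stringsAsFactors = FALSE)
  list(shift = nrow(detail) > 0L, detail = detail)
}

#' Copy-number event flags at configured loci
#'
#' Community-convention calls from allele-specific segments: gain1q is
#' total copy number exactly 3 at the 1q21 locus, amp1q21 is total copy
#' number >= 4, del17p is total copy number < 2 at the 17p locus. Locus
#' coordinates are configuration (defaults use toy coordinates matched to
#' the simulator's contigs; supply genome-build coordinates for real
#' data).
#'
#' @param segments segment data.frame (\code{chrom}, \code{start},
#'   \code{end}, \code{total_cn}).
#' @param loci named list of \code{list(chrom=, start=, end=)} for
#'   \code{locus_1q21} and \code{locus_17p}.
#' @return named logical vector: \code{gain1q}, \code{amp1q21},
#'   \code{del17p}.
#' @export
cn_event_flags <- function(segments,
                           loci = list(
                             locus_1q21 = list(chrom = "1", start = 150e6,
                                               end = 155e6),
                             locus_17p = list(chrom = "17", start = 1,
                                              end = 10e6))) {
  locus_cn <- function(locus) {
    hit <- segments$chrom == locus$chrom &
      segments$start <= locus$end & segments$end >= locus$start
    if (!any(hit)) return(NA_integer_)
    max(segments$total_cn[hit])
  }
  cn1q <- locus_cn(loci$locus_1q21)
  cn17p <- locus_cn(loci$locus_17p)
  c(gain1q = !is.na(cn1q) && cn1q == 3L,
    amp1q21 = !is.na(cn1q) && cn1q >= 4L,
    del17p = !is.na(cn17p) && cn17p < 2L)
}
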