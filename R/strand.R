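#' Transcriptional strand assignment and stranded channel counts
#'
#' Classifies each context-annotated mutation falling inside an annotated
#' transcript as occurring on the transcribed (template) or untranscribed
#' (coding/sense) strand, and tabulates counts per SBS-96 channel and
#' strand. The convention follows signature-analysis practice: channels
#' are pyrimidine-normalized, so the strand carrying the pyrimidine of the
#' mutated pair determines the label. If the pyrimidine lies on the
#' transcript's sense strand the mutation is counted as "untranscribed";
#' if it lies on the template strand, as "transcribed". Mutations outside
#' all transcripts are intergenic and excluded; mutations overlapping
#' transcripts on both strands are ambiguous and also excluded.
#'
#' @param muts context-annotated mutation data.frame.
#' @param tx transcript intervals: a BED-like data.frame with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{strand} (0-based
#'   half-open starts, strand "+" or "-"), a path to such a file
#'   (tab-separated, with or without header), or a
#'   \code{GenomicRanges::GRanges}.
#' @return a \code{stranded_counts} object: a 96 x 2 integer matrix
#'   (channels x c("transcribed", "untranscribed")) with attributes
#'   \code{n_intergenic} and \code{n_ambiguous}.
#' @export
stranded_counts <- function(muts, tx) {
  tx_gr <- as_tx_granges(tx)
  channels <- sbs96_channels()
  out <- matrix(0L, nrow = 96, ncol = 2,
                dimnames = list(channels, c("transcribed", "untranscribed")))
  keep <- !is.na(muts$context) & !grepl("[^ACGT]", muts$context)
  muts <- muts[keep, , drop = FALSE]
  if (nrow(muts) == 0L) {
    return(structure(out, class = "stranded_counts",
                     n_intergenic = 0L, n_ambiguous = 0L))
  }
  mut_gr <- GenomicRanges::GRanges(
    muts$chrom, IRanges::IRanges(muts$pos, muts$pos))
  hits <- GenomicRanges::findOverlaps(mut_gr, tx_gr, ignore.strand = TRUE)
  strand_by_mut <- lapply(split(
    as.character(GenomicRanges::strand(tx_gr))[S4Vectors_subjectHits(hits)],
    factor(S4Vectors_queryHits(hits), levels = seq_len(nrow(muts)))),
    unique)
  n_strands <- lengths(strand_by_mut)
  genic <- n_strands == 1L
  ambiguous <- n_strands > 1L
  if (any(genic)) {
    gene_strand <- vapply(strand_by_mut[genic], `[`, "", 1L)
    ch <- channel_of(muts$ref[genic], muts$alt[genic], muts$context[genic])
    pyr_strand <- ifelse(muts$ref[genic] %in% c("C", "T"), "+", "-")
    label <- ifelse(pyr_strand == gene_strand, "untranscribed", "transcribed")
    tab <- table(factor(ch, levels = channels),
                 factor(label, levels = c("transcribed", "untranscribed")))
    out[] <- as.integer(tab)
  }
  structure(out, class = "stranded_counts",
            n_intergenic = sum(!genic & !ambiguous),
            n_ambiguous = sum(ambiguous))
}

# findOverlaps accessors without importing all of S4Vectors
S4Vectors_queryHits <- function(h) S4Vectors::queryHits(h)
S4Vectors_subjectHits <- function(h) S4Vectors::subjectHits(h)

as_tx_granges <- function(tx) {
  if (inherits(tx, "GRanges")) return(tx)
  if (is.character(tx) && length(tx) == 1L) {
    first <- readLines(tx, n = 1L)
    header <- grepl("chrom", first, ignore.case = TRUE)
    df <- tryCatch(
      utils::read.delim(tx, header = header, stringsAsFactors = FALSE),
      error = function(e) stop("malformed interval file: ", tx))
    if (!header) {
      if (ncol(df) < 4L) stop("malformed interval file: ", tx,
                              " (need chrom, start, end, strand)")
      # BED order: chrom start end [name score] strand
      strand_col <- if (ncol(df) >= 6L) 6L else 4L
      df <- data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
                       strand = df[[strand_col]], stringsAsFactors = FALSE)
    }
    tx <- df
  }
  required <- c("chrom", "start", "end", "strand")
  if (!all(required %in% names(tx))) {
    stop("interval table needs columns: ", paste(required, collapse = ", "))
  }
  if (!all(tx$strand %in% c("+", "-"))) {
    stop("interval strand must be '+' or '-'")
  }
  if (any(tx$start < 0L | tx$end <= tx$start)) {
    stop("intervals must be 0-based half-open with start < end")
  }
  # convert 0-based half-open to the 1-based inclusive coordinates GRanges uses
  GenomicRanges::GRanges(
    tx$chrom, IRanges::IRanges(tx$start + 1L, tx$end), strand = tx$strand)
}

#' @export
print.stranded_counts <- function(x, ...) {
  cat("Stranded SBS-96 counts: transcribed =", sum(x[, "transcribed"]),
      ", untranscribed =", sum(x[, "untranscribed"]),
      "\n  intergenic excluded:", attr(x, "n_intergenic"),
      " ambiguous excluded:", attr(x, "n_ambiguous"), "\n")
  invisible(x)
}

#' Write stranded counts to TSV
#' @param sc a \code{stranded_counts} object.
#' @param path output file.
#' @export
write_stranded_counts <- function(sc, path) {
  utils::write.table(
    data.frame(channel = rownames(sc),
               transcribed = sc[, "transcribed"],
               untranscribed = sc[, "untranscribed"]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
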