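#' SBS-96 channel conventions
#'
#' Single-base substitutions are classified into 96 channels by the
#' pyrimidine-normalized substitution class (C>A, C>G, C>T, T>A, T>C, T>G)
#' and the two flanking reference bases. When the mutated reference base is
#' a purine, the mutation and its trinucleotide context are
#' reverse-complemented first, so every substitution is reported from the
#' pyrimidine strand. Channel labels follow the de-facto standard
#' \code{"X[R>A]Y"} layout used by COSMIC-style signature matrices:
#' substitution classes in the order C>A, C>G, C>T, T>A, T>C, T>G, and
#' within each class the 16 flank combinations in lexicographic order.
#'
#' @return \code{sbs96_channels()} returns the 96 channel labels in
#'   canonical order.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(x, y) {
      paste0(x, "[", s, "]", y)
    })))
  }))
}

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Vectorized over its input; used for pyrimidine normalization of
#' substitution channels.
#' @param x character vector of DNA strings (A/C/G/T only).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1))
}

#' Assign the SBS-96 channel of a substitution
#'
#' @param ref,alt single reference/alternate bases (vectorized).
#' @param context the reference-strand trinucleotide centered on the
#'   mutated base; its middle base must equal \code{ref}.
#' @return character vector of channel labels, e.g. \code{"A[C>T]G"}.
#' @examples
#' channel_of("C", "T", "ACA")  # "A[C>T]A"
#' channel_of("G", "A", "AGT")  # "A[C>T]T" after reverse complement
#' @export
channel_of <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  context <- rep_len(toupper(context), n)
  if (!all(ref %in% BASES) || !all(alt %in% BASES)) {
    stop("ref and alt must be single bases in {A,C,G,T}")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  if (any(nchar(context) != 3L) ||
      !all(strsplit(paste(context, collapse = ""), "")[[1]] %in% BASES)) {
    stop("context must be 3-mers over {A,C,G,T}")
  }
  if (any(substr(context, 2, 2) != ref)) {
    stop("context middle base must equal ref")
  }
  purine <- ref %in% c("A", "G")
  ref[purine] <- chartr("AG", "TC", ref[purine])
  alt[purine] <- chartr("ACGT", "TGCA", alt[purine])
  context[purine] <- revcomp(context[purine])
  paste0(substr(context, 1, 1), "[", ref, ">", alt, "]",
         substr(context, 3, 3))
}

#' Build a 96-channel trinucleotide catalog
#'
#' Counts context-annotated somatic SNVs into the canonical SBS-96
#' channels. Records flagged unclassifiable (missing context, context
#' containing N, or at a contig edge) are excluded; the catalog total
#' equals the number of classifiable records.
#'
#' @param muts mutation table as returned by [read_mutations()] /
#'   [annotate_context()]: a data.frame with at least \code{ref},
#'   \code{alt} and \code{context} columns.
#' @param sample_id sample label stored on the catalog; defaults to the
#'   table's single \code{sample_id} value when unambiguous.
#' @return an \code{sbs_catalog}: a named integer vector of length 96 in
#'   canonical channel order, with attributes \code{sample_id} and
#'   \code{n_unclassifiable}.
#' @export
build_catalog <- function(muts, sample_id = NULL) {
  channels <- sbs96_channels()
  if (is.null(sample_id)) {
    sid <- unique(as.character(muts$sample_id))
    sample_id <- if (length(sid) == 1L) sid else NA_character_
  }
  counts <- stats::setNames(integer(96), channels)
  n_unclass <- 0L
  if (nrow(muts) > 0L) {
    ctx <- as.character(muts$context)
    ok <- !is.na(ctx) & nchar(ctx) == 3L & !grepl("[^ACGT]", ctx)
    n_unclass <- sum(!ok)
    if (any(ok)) {
      ch <- channel_of(muts$ref[ok], muts$alt[ok], ctx[ok])
      tab <- table(factor(ch, levels = channels))
      counts <- stats::setNames(as.integer(tab), channels)
    }
  }
  structure(counts, class = "sbs_catalog",
            sample_id = sample_id, n_unclassifiable = n_unclass)
}

#' @export
print.sbs_catalog <- function(x, ...) {
  cat("SBS-96 catalog", if (!is.na(attr(x, "sample_id")))
    paste0("[", attr(x, "sample_id"), "]"), "\n")
  cat("  total mutations:", sum(x),
      " unclassifiable:", attr(x, "n_unclassifiable"), "\n")
  top <- sort(x[x > 0], decreasing = TRUE)
  cat("  top channels:",
      paste(utils::head(names(top), 5), utils::head(top, 5),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Coerce a 96-vector of counts to an \code{sbs_catalog}
#'
#' @param counts numeric vector of length 96, optionally named by
#'   channel (any order); unnamed vectors are assumed canonical.
#' @param sample_id sample label.
#' @return an \code{sbs_catalog}.
#' @export
as_catalog <- function(counts, sample_id = NA_character_) {
  channels <- sbs96_channels()
  stopifnot(length(counts) == 96L)
  if (!is.null(names(counts))) {
    if (!identical(names(counts), channels)) {
      if (!setequal(names(counts), channels)) {
        stop("counts must be named by the 96 canonical channels")
      }
      counts <- counts[channels]
    }
  } else {
    names(counts) <- channels
  }
  structure(as.integer(round(counts)), names = channels,
            class = "sbs_catalog", sample_id = sample_id,
            n_unclassifiable = 0L)
}

#' Write / read a catalog TSV (channel, count; fixed channel order)
#' @param catalog an \code{sbs_catalog}.
#' @param path output file.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(
    data.frame(channel = names(catalog), count = as.integer(catalog)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_catalog(stats::setNames(df$count, df$channel))
}
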