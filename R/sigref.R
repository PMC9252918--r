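#' Signature reference matrices
#'
#' A signature reference is a numeric matrix (signatures x 96 channels) in
#' canonical channel order where every row is a probability vector. Real
#' references (e.g. COSMIC SBS matrices) are user-supplied TSV files; the
#' package ships a deterministic 5-signature toy reference for testing and
#' simulation, including a melphalan-like "SBS-MM1" profile concentrated on
#' C>T mutations in the CCA, GCA, GCC, GCG and GCT contexts.
#'
#' @param path TSV with the channel labels in the first column and one
#'   column per signature.
#' @return a \code{signature_reference}: matrix with signature row names
#'   and channel column names.
#' @export
read_signature_reference <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  channels <- df[[1]]
  mat <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(mat) <- channels
  as_signature_reference(mat)
}

#' @param mat signatures x 96 numeric matrix, columns named by channel.
#' @rdname read_signature_reference
#' @export
as_signature_reference <- function(mat) {
  channels <- sbs96_channels()
  if (ncol(mat) != 96L) stop("signature reference must have 96 channels")
  if (!is.null(colnames(mat))) {
    if (!setequal(colnames(mat), channels)) {
      stop("signature reference channels do not match the canonical order")
    }
    mat <- mat[, channels, drop = FALSE]
  } else {
    colnames(mat) <- channels
  }
  if (any(mat < 0)) stop("signature profiles must be nonnegative")
  rs <- rowSums(mat)
  if (any(abs(rs - 1) > 1e-8)) {
    stop("every signature profile must sum to 1 (within 1e-8)")
  }
  structure(mat, class = c("signature_reference", class(mat)))
}

#' Write a signature reference TSV (channel first column)
#' @param ref a \code{signature_reference}.
#' @param path output file.
#' @export
write_signature_reference <- function(ref, path) {
  df <- data.frame(channel = colnames(ref), t(ref), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Built-in toy signature reference
#'
#' Five deterministic synthetic profiles loosely shaped after recognizable
#' signature classes: a CpG deamination-like C>T signature ("SIG1"), a
#' T>C-dominated background ("SIG5"), an APOBEC-like TpC signature
#' ("SIGA"), a C>A-dominated signature ("SIG8"), and "SBS-MM1", a
#' melphalan-like profile with half its mass on C>T in the CCA, GCA, GCC,
#' GCG and GCT contexts plus a T>A component. Intended for tests and
#' simulations; real analyses should load a published reference matrix.
#'
#' @return a \code{signature_reference} with rows SIG1, SIG5, SIGA, SIG8,
#'   SBS-MM1.
#' @export
toy_signature_reference <- function() {
  channels <- sbs96_channels()
  blank <- stats::setNames(numeric(96), channels)
  uniform <- rep(1 / 96, 96)

  sig1 <- blank
  sig1[paste0(c("A", "C", "G", "T"), "[C>T]G")] <- 0.8 / 4
  sig1 <- sig1 + 0.2 * uniform

  sig5 <- blank
  sig5[grep("\\[T>C\\]", channels)] <- 0.6 / 16
  sig5 <- sig5 + 0.4 * uniform

  siga <- blank
  siga[c("T[C>G]A", "T[C>G]T")] <- 0.4 / 2
  siga[c("T[C>T]A", "T[C>T]T")] <- 0.4 / 2
  siga <- siga + 0.2 * uniform

  sig8 <- blank
  sig8[grep("\\[C>A\\]", channels)] <- 0.6 / 16
  sig8 <- sig8 + 0.4 * uniform

  mm1 <- blank
  mm1[mm1_channels()] <- 0.5 / 5
  mm1[grep("\\[T>A\\]", channels)] <- 0.25 / 16
  mm1 <- mm1 + 0.25 * uniform

  mat <- rbind(SIG1 = sig1, SIG5 = sig5, SIGA = siga, SIG8 = sig8,
               `SBS-MM1` = mm1)
  colnames(mat) <- channels
  as_signature_reference(mat)
}

#' The five C>T contexts characteristic of the melphalan signature
#'
#' @param contexts raw trinucleotides (5' base, mutated C, 3' base);
#'   defaults to CCA, GCA, GCC, GCG, GCT.
#' @return the corresponding C>T channel labels.
#' @export
mm1_channels <- function(contexts = c("CCA", "GCA", "GCC", "GCG", "GCT")) {
  if (any(substr(contexts, 2, 2) != "C")) {
    stop("melphalan-context trinucleotides must be centered on C")
  }
  paste0(substr(contexts, 1, 1), "[C>T]", substr(contexts, 3, 3))
}
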