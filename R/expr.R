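#' Expression matrix I/O and z-scoring
#'
#' Expression matrices are plain numeric matrices with gene symbols as
#' row names and sample ids as column names, on the TPM scale unless
#' stated otherwise. Gene identifiers are case-sensitive plain symbols;
#' alias mapping is the caller's job.
#'
#' @param path TSV with genes in the first column, one column per sample.
#' @return numeric matrix (genes x samples).
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  validate_expression(m)
}

validate_expression <- function(m) {
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids")
  if (any(!is.finite(m))) stop("expression values must be finite")
  if (any(m < 0)) stop("TPM values must be nonnegative")
  m
}

#' Write an expression TSV (gene first column)
#' @param m genes x samples matrix.
#' @param path output file.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Center and scale expression per gene across samples
#'
#' Optionally log-transforms TPM as log2(TPM + 1), then standardizes each
#' gene to mean 0 and sd 1 across samples. Zero-variance genes are set to
#' 0 and listed in the \code{flat_genes} attribute. This is the
#' normalization applied before single-sample enrichment scoring, so
#' scores emphasize relative differences between samples.
#'
#' @param m genes x samples matrix (TPM scale unless
#'   \code{log_transform = FALSE} and already transformed).
#' @param log_transform apply log2(TPM + 1) first (default TRUE).
#' @return z-scored matrix of the same shape.
#' @export
zscore_across_samples <- function(m, log_transform = TRUE) {
  if (ncol(m) < 2L) stop("z-scoring across samples needs >= 2 samples")
  if (log_transform) m <- log2(m + 1)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  flat <- sdv == 0
  sdv[flat] <- 1
  z <- (m - mu) / sdv
  z[flat, ] <- 0
  attr(z, "flat_genes") <- rownames(m)[flat]
  z
}

#' Read / write gene sets in GMT format
#'
#' @param path GMT file (set name, description, then genes, tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @param sets named list of character vectors.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Built-in gene panels
#'
#' Loads the reconstructed gene panels shipped with the package:
#' the 11-gene proliferation index panel, 27 hematological cancer
#' germline antigens, an NFkB index panel, HLA class I/II panels, ABC
#' transporters and exportins. The lists are reconstructed from the
#' literature sources the field commonly cites and are intentionally
#' editable data files, not code.
#'
#' @param panel optional single panel name; by default all panels are
#'   returned as a named list.
#' @return named list of character vectors (or one character vector).
#' @export
builtin_panels <- function(panel = NULL) {
  path <- system.file("extdata", "panels_reconstructed.gmt",
                      package = "mmclonetrack")
  sets <- read_gmt(path)
  if (is.null(panel)) return(sets)
  if (!panel %in% names(sets)) {
    stop("unknown panel: ", panel, " (available: ",
         paste(names(sets), collapse = ", "), ")")
  }
  sets[[panel]]
}
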