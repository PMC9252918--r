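#' Read somatic SNVs from a VCF or mutation TSV
#'
#' Returns a mutation table (one row per single-base substitution) with the
#' columns \code{patient_id}, \code{sample_id}, \code{chrom}, \code{pos}
#' (1-based), \code{ref}, \code{alt}, \code{alt_reads}, \code{total_reads},
#' \code{vaf}, and the optional columns \code{context}, \code{tx_strand},
#' \code{gene}, \code{rna_alt_reads} when present in the source. Non-SNV
#' records (indels, multi-allelic sites that are not simple substitutions)
#' are skipped and the skip count is reported via a message and stored in
#' the \code{n_skipped} attribute.
#'
#' For VCF input, read support is taken from the FORMAT \code{AD} field
#' (ref,alt depths) of the requested sample column, falling back to
#' \code{DP} + \code{AF} when \code{AD} is absent. For TSV input an
#' explicit \code{vaf} column takes precedence; otherwise VAF is computed
#' as \code{alt_reads / total_reads}.
#'
#' @param path a VCF (\code{.vcf}) or tab-separated mutation table.
#' @param sample_id sample label attached to each record; for VCF it also
#'   selects the genotype column (defaults to the first sample).
#' @param patient_id optional patient label.
#' @return a validated mutation data.frame.
#' @export
read_mutations <- function(path, sample_id = NULL, patient_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    muts <- read_mutations_vcf(path, sample_id)
  } else {
    muts <- read_mutations_tsv(path, sample_id)
  }
  if (is.na(patient_id) && is.null(muts$patient_id)) {
    muts$patient_id <- NA_character_
  } else if (!is.na(patient_id)) {
    muts$patient_id <- patient_id
  }
  validate_mutations(muts)
}

read_mutations_tsv <- function(path, sample_id = NULL) {
  # read everything as character first: a column holding only "T" would
  # otherwise be parsed as logical TRUE
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) stop("unparseable mutation table: ", path, " (",
                             conditionMessage(e), ")"))
  for (col in intersect(c("pos", "alt_reads", "total_reads",
                          "rna_alt_reads"), names(df))) {
    df[[col]] <- as.integer(df[[col]])
  }
  if ("vaf" %in% names(df)) df$vaf <- as.numeric(df$vaf)
  required <- c("chrom", "pos", "ref", "alt")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("mutation table ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  }
  is_snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    df$ref %in% BASES & df$alt %in% BASES
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0L) {
    message("read_mutations: skipped ", n_skipped, " non-SNV records")
  }
  df <- df[is_snv, , drop = FALSE]
  if (!is.null(sample_id)) df$sample_id <- sample_id
  if (is.null(df$sample_id)) df$sample_id <- NA_character_
  if (is.null(df$vaf)) {
    if (is.null(df$alt_reads) || is.null(df$total_reads)) {
      stop("mutation table needs either a vaf column or alt_reads/total_reads")
    }
    df$vaf <- df$alt_reads / df$total_reads
  }
  attr(df, "n_skipped") <- n_skipped
  df
}

read_mutations_vcf <- function(path, sample_id = NULL) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("unparseable VCF: ", path))
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(empty_mutation_table())
  }
  is_snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% BASES & fix$ALT %in% BASES
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0L) {
    message("read_mutations: skipped ", n_skipped, " non-SNV records")
  }
  gt_samples <- colnames(vcf@gt)[-1]
  use_sample <- if (!is.null(sample_id) && sample_id %in% gt_samples) {
    sample_id
  } else {
    gt_samples[1]
  }
  ad <- tryCatch(
    vcfR::extract.gt(vcf, element = "AD")[, use_sample],
    error = function(e) rep(NA_character_, nrow(fix)))
  alt_reads <- total_reads <- rep(NA_integer_, nrow(fix))
  has_ad <- !is.na(ad)
  if (any(has_ad)) {
    parts <- strsplit(ad[has_ad], ",", fixed = TRUE)
    alt_reads[has_ad] <- as.integer(vapply(parts, `[`, "", 2L))
    total_reads[has_ad] <- as.integer(vapply(parts, `[`, "", 1L)) +
      alt_reads[has_ad]
  }
  if (any(!has_ad)) {
    dp <- suppressWarnings(as.integer(
      vcfR::extract.gt(vcf, element = "DP")[, use_sample]))
    af <- suppressWarnings(as.numeric(
      vcfR::extract.gt(vcf, element = "AF")[, use_sample]))
    total_reads[!has_ad] <- dp[!has_ad]
    alt_reads[!has_ad] <- as.integer(round(dp[!has_ad] * af[!has_ad]))
  }
  df <- data.frame(
    sample_id = if (is.null(sample_id)) use_sample else sample_id,
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    alt_reads = alt_reads, total_reads = total_reads,
    stringsAsFactors = FALSE)
  df <- df[is_snv, , drop = FALSE]
  df$vaf <- df$alt_reads / df$total_reads
  attr(df, "n_skipped") <- n_skipped
  df
}

empty_mutation_table <- function() {
  data.frame(sample_id = character(), chrom = character(),
             pos = integer(), ref = character(), alt = character(),
             alt_reads = integer(), total_reads = integer(),
             vaf = numeric(), stringsAsFactors = FALSE)
}

#' Validate a mutation table
#'
#' Enforces the record invariants: single-base ref/alt over {A,C,G,T} with
#' ref != alt, positive read totals, VAF in [0,1] consistent with the
#' depths (within 1e-9) when both are given, and the context (when
#' present) centered on the reference base.
#'
#' @param muts mutation data.frame.
#' @return the table, invisibly unchanged, or an error describing the
#'   first violated invariant.
#' @export
validate_mutations <- function(muts) {
  if (nrow(muts) == 0L) return(muts)
  if (any(nchar(muts$ref) != 1L | nchar(muts$alt) != 1L |
          !(muts$ref %in% BASES) | !(muts$alt %in% BASES))) {
    stop("ref/alt must be single bases in {A,C,G,T}")
  }
  if (any(muts$ref == muts$alt)) stop("ref must differ from alt")
  if (any(muts$pos < 1L)) stop("positions are 1-based and must be >= 1")
  if (!is.null(muts$total_reads)) {
    has_depth <- !is.na(muts$total_reads)
    if (any(has_depth & muts$total_reads <= 0L)) {
      stop("total_reads must be positive")
    }
    if (any(has_depth & (muts$alt_reads < 0L |
                         muts$alt_reads > muts$total_reads))) {
      stop("alt_reads must lie in [0, total_reads]")
    }
    both <- has_depth & !is.na(muts$vaf)
    if (any(abs(muts$vaf[both] -
                muts$alt_reads[both] / muts$total_reads[both]) > 1e-9)) {
      stop("vaf inconsistent with alt_reads/total_reads")
    }
  }
  if (any(is.na(muts$vaf) | muts$vaf < 0 | muts$vaf > 1)) {
    stop("vaf must lie in [0, 1]")
  }
  if (!is.null(muts$context)) {
    ctx <- muts$context
    ok <- is.na(ctx) | nchar(ctx) != 3L | grepl("[^ACGT]", ctx)
    chk <- !ok  # well-formed ACGT 3-mers must be centered on ref
    if (any(chk & substr(ctx, 2, 2) != muts$ref)) {
      stop("context middle base must equal ref")
    }
  }
  muts
}

#' Annotate trinucleotide contexts from a reference genome
#'
#' Looks up the forward-strand trinucleotide centered on each mutation
#' position. Records that already carry a context are left untouched.
#' Positions at a contig edge (pos 1 or the last base) and contexts
#' containing N are marked unclassifiable (\code{context = NA}).
#'
#' @param muts mutation data.frame.
#' @param reference path to a FASTA file or a
#'   \code{Biostrings::DNAStringSet}.
#' @return the table with \code{context} filled in and a logical
#'   \code{classifiable} column.
#' @export
annotate_context <- function(muts, reference) {
  genome <- if (inherits(reference, "DNAStringSet")) {
    reference
  } else {
    Biostrings::readDNAStringSet(reference)
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.null(muts$context)) muts$context <- NA_character_
  need <- is.na(muts$context)
  if (any(need)) {
    missing_contig <- setdiff(unique(muts$chrom[need]), names(genome))
    if (length(missing_contig)) {
      stop("contig(s) absent from reference: ",
           paste(missing_contig, collapse = ", "))
    }
    lens <- Biostrings::width(genome)[match(muts$chrom, names(genome))]
    at_edge <- need & (muts$pos < 2L | muts$pos > lens - 1L)
    idx <- which(need & !at_edge)
    if (length(idx)) {
      ctx <- as.character(Biostrings::subseq(
        genome[muts$chrom[idx]],
        start = muts$pos[idx] - 1L, end = muts$pos[idx] + 1L))
      bad_center <- substr(ctx, 2, 2) != muts$ref[idx]
      if (any(bad_center)) {
        warning(sum(bad_center),
                " record(s) disagree with the reference base; ",
                "marked unclassifiable")
        ctx[bad_center] <- NA_character_
      }
      ctx[grepl("[^ACGT]", ctx)] <- NA_character_
      muts$context[idx] <- ctx
    }
  }
  muts$classifiable <- !is.na(muts$context) &
    !grepl("[^ACGT]", muts$context)
  muts
}
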