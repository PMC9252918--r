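test_that("channel assignment matches the reverse-complement oracle on all 192 raw cases", {
  bases <- c("A", "C", "G", "T")
  for (ref in bases) for (alt in setdiff(bases, ref)) {
    for (l in bases) for (r in bases) {
      ctx <- paste0(l, ref, r)
      expect_identical(channel_of(ref, alt, ctx),
                       oracle_channel(ref, alt, ctx))
      rc <- oracle_revcomp_triplet(ref, alt, ctx)
      expect_identical(channel_of(ref, alt, ctx),
                       channel_of(rc$ref, rc$alt, rc$ctx))
    }
  }
})

test_that("channel_of handles pyrimidine and purine representations", {
  expect_identical(channel_of("C", "T", "ACA"), "A[C>T]A")
  expect_identical(channel_of("G", "A", "AGT"), "A[C>T]T")
  expect_identical(channel_of("T", "G", "CTG"), "C[T>G]G")
  expect_error(channel_of("C", "C", "ACA"), "differ")
  expect_error(channel_of("C", "T", "AGA"), "middle base")
  expect_error(channel_of("C", "N", "ACA"))
})

test_that("catalog counts equal a naive per-record recount and conserve totals", {
  set.seed(101)
  channels <- sbs96_channels()
  n <- 500L
  ch <- sample(channels, n, replace = TRUE)
  muts <- mmclonetrack:::mutation_records_from_channels(ch, "s1")
  cat <- build_catalog(muts)
  # naive recount oracle
  recount <- table(factor(vapply(seq_len(n), function(i) {
    oracle_channel(muts$ref[i], muts$alt[i], muts$context[i])
  }, character(1)), levels = channels))
  expect_identical(as.integer(cat), as.integer(recount))
  expect_identical(sum(cat), n)
  # unclassifiable records (N in context) excluded but counted
  muts$context[1:7] <- "ANA"
  cat2 <- build_catalog(muts)
  expect_identical(sum(cat2) + attr(cat2, "n_unclassifiable"), n)
  expect_identical(attr(cat2, "n_unclassifiable"), 7L)
})

test_that("empty and single-channel catalogs behave", {
  empty <- build_catalog(data.frame())
  expect_true(all(empty == 0L))
  muts <- data.frame(sample_id = "s", chrom = "c", pos = 1:5,
                     ref = "C", alt = "T", alt_reads = 5L,
                     total_reads = 10L, vaf = 0.5, context = "ACA")
  cat <- build_catalog(muts)
  expect_identical(unname(cat["A[C>T]A"]), 5L)
  expect_identical(sum(cat), 5L)
})

test_that("catalogs round-trip through TSV", {
  set.seed(102)
  cat <- as_catalog(rpois(96, 4), sample_id = "s1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat, path)
  back <- read_catalog(path)
  expect_identical(as.integer(back), as.integer(cat))
  expect_identical(names(back), sbs96_channels())
})

test_that("TSV mutation tables are read with explicit or derived VAF", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\talt_reads\ttotal_reads\tvaf",
               "chr1\t100\tC\tT\t5\t20\t0.25",
               "chr1\t200\tG\tA\t10\t40\t0.25",
               "chr1\t300\tAC\tA\t3\t30\t0.1"), path)
  expect_message(muts <- read_mutations(path, sample_id = "s1"),
                 "skipped 1")
  expect_identical(nrow(muts), 2L)
  expect_equal(muts$vaf, c(0.25, 0.25))
  # derived VAF when the column is absent
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\talt_reads\ttotal_reads",
               "chr1\t100\tC\tT\t5\t20"), path2)
  expect_equal(read_mutations(path2, sample_id = "s")$vaf, 0.25)
})

test_that("invalid mutation records are rejected", {
  bad <- data.frame(sample_id = "s", chrom = "c", pos = 1L, ref = "C",
                    alt = "C", alt_reads = 1L, total_reads = 2L,
                    vaf = 0.5)
  expect_error(validate_mutations(bad), "differ")
  bad2 <- data.frame(sample_id = "s", chrom = "c", pos = 1L, ref = "C",
                     alt = "T", alt_reads = 1L, total_reads = 2L,
                     vaf = 0.9)
  expect_error(validate_mutations(bad2), "inconsistent")
})

test_that("VCF SNVs are parsed with AD depths and indels skipped", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="AD">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR",
    "chr1\t100\t.\tC\tT\t.\tPASS\t.\tGT:AD\t0/1:15,5",
    "chr1\t200\t.\tG\tA\t.\tPASS\t.\tGT:AD\t0/1:30,10",
    "chr1\t300\t.\tT\tG\t.\tPASS\t.\tGT:AD\t0/1:18,2",
    "chr1\t400\t.\tCA\tC\t.\tPASS\t.\tGT:AD\t0/1:20,4"), path)
  expect_message(muts <- read_mutations(path, sample_id = "TUMOR"),
                 "skipped 1")
  expect_identical(nrow(muts), 3L)
  expect_identical(attr(muts, "n_skipped"), 1L)
  expect_equal(muts$vaf, c(5 / 20, 10 / 40, 2 / 20))
  expect_identical(muts$pos, c(100L, 200L, 300L))
})

test_that("contexts are read off the reference and edges flagged", {
  fa <- Biostrings::DNAStringSet(c(ctgA = "ACGTACGT"))
  muts <- data.frame(sample_id = "s", chrom = "ctgA",
                     pos = c(2L, 1L, 5L), ref = c("C", "A", "A"),
                     alt = c("T", "T", "G"),
                     alt_reads = 1L, total_reads = 2L, vaf = 0.5)
  ann <- annotate_context(muts, fa)
  expect_identical(ann$context[1], "ACG")
  expect_true(is.na(ann$context[2]))  # contig edge
  expect_identical(ann$context[3], "TAC")
  expect_identical(ann$classifiable, c(TRUE, FALSE, TRUE))
  # pre-annotated records untouched
  muts$context <- c("CCC", NA, NA)
  ann2 <- annotate_context(muts, fa)
  expect_identical(ann2$context[1], "CCC")
  expect_identical(ann2$context[3], "TAC")
  # missing contig is an error naming the contig
  muts$chrom <- "ctgB"
  muts$context <- NULL
  expect_error(annotate_context(muts, fa), "ctgB")
})

test_that("transcriptional strand labels follow the pyrimidine convention", {
  # one + strand gene [0, 1000) and one - strand gene [2000, 3000)
  tx <- data.frame(chrom = "c", start = c(0L, 2000L),
                   end = c(1000L, 3000L), strand = c("+", "-"))
  mk <- function(pos, ref, alt, ctx) {
    data.frame(sample_id = "s", chrom = "c", pos = pos, ref = ref,
               alt = alt, alt_reads = 1L, total_reads = 2L, vaf = 0.5,
               context = ctx)
  }
  # C>T with pyrimidine on + inside + gene: sense strand -> untranscribed
  sc <- stranded_counts(mk(100L, "C", "T", "ACA"), tx)
  expect_identical(unname(sc["A[C>T]A", "untranscribed"]), 1L)
  # G>A (pyrimidine on -) inside + gene -> transcribed
  sc <- stranded_counts(mk(100L, "G", "A", "TGT"), tx)
  expect_identical(unname(sc["A[C>T]A", "transcribed"]), 1L)
  # C>T inside - gene -> transcribed
  sc <- stranded_counts(mk(2500L, "C", "T", "ACA"), tx)
  expect_identical(unname(sc["A[C>T]A", "transcribed"]), 1L)
  # G>A inside - gene -> untranscribed
  sc <- stranded_counts(mk(2500L, "G", "A", "TGT"), tx)
  expect_identical(unname(sc["A[C>T]A", "untranscribed"]), 1L)
  # intergenic excluded
  sc <- stranded_counts(mk(1500L, "C", "T", "ACA"), tx)
  expect_true(all(sc == 0L))
  expect_identical(attr(sc, "n_intergenic"), 1L)
  # genes on both strands -> ambiguous, excluded
  tx2 <- rbind(tx, data.frame(chrom = "c", start = 0L, end = 1000L,
                              strand = "-"))
  sc <- stranded_counts(mk(100L, "C", "T", "ACA"), tx2)
  expect_true(all(sc == 0L))
  expect_identical(attr(sc, "n_ambiguous"), 1L)
})

test_that("stranded marginals never exceed catalog counts", {
  set.seed(103)
  sim <- simulate_catalog(400, c(SIG1 = 0.4, `SBS-MM1` = 0.6))
  cat <- sim$catalog
  sc <- tabulate_stranded(sim$mutations)
  expect_true(all(rowSums(sc) <= as.integer(cat)))
})

test_that("BED-dialect boundaries convert correctly (0-based half-open)", {
  tx <- data.frame(chrom = "c", start = 10L, end = 20L, strand = "+")
  mk <- function(pos) data.frame(sample_id = "s", chrom = "c", pos = pos,
                                 ref = "C", alt = "T", alt_reads = 1L,
                                 total_reads = 2L, vaf = 0.5,
                                 context = "ACA")
  # 0-based [10, 20) covers 1-based positions 11..20
  expect_identical(sum(stranded_counts(mk(10L), tx)), 0L)
  expect_identical(sum(stranded_counts(mk(11L), tx)), 1L)
  expect_identical(sum(stranded_counts(mk(20L), tx)), 1L)
  expect_identical(sum(stranded_counts(mk(21L), tx)), 0L)
})
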