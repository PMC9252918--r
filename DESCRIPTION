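Package: mmclonetrack
Title: Clonal Evolution and Transcriptomic Scoring of Paired Myeloma Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of paired early/late multiple myeloma tumor samples:
    construction of SBS-96 trinucleotide mutation catalogs from somatic SNVs,
    maximum-likelihood mutational signature refitting with bootstrap
    confidence intervals and melphalan-signature (SBS-MM1) presence calls,
    transcriptional strand-bias testing, cancer-cell-fraction estimation and
    Gaussian-mixture subclonal clustering of paired timepoints,
    stable/linear/differential clonal-evolution classification and RAS-shift
    detection, and a transcriptomic scoring layer (single-sample GSEA on
    z-scored TPM, an 11-gene proliferation index with change thresholds,
    cancer-germline-antigen counting, gene-panel indices, fold changes and
    Spearman correlation summaries). A synthetic-data module generates
    cohorts with known ground truth for every stage, and a pipeline
    orchestrates the full per-patient analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    fgsea,
    jsonlite,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
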