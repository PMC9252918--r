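#' Synthetic-data generators with known ground truth
#'
#' The simulators emulate the statistical structure of a paired-sample
#' myeloma study: 96-channel catalogs drawn from known signature mixtures
#' (including a melphalan-like signature with transcriptional strand
#' asymmetry in its characteristic C>T contexts), paired variant sets
#' whose CCFs come from planted cluster layouts under each clonal
#' evolution scenario, and TPM matrices with planted shifts in gene
#' panels. Every generator is deterministic under a fixed seed, and the
#' returned ground truth is sufficient to score downstream recovery
#' without re-reading the configuration.
#'
#' @name simdata
NULL

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  code
}

#' Simulate a mutation catalog from a signature mixture
#'
#' Draws \code{n_mutations} channels multinomially from the convex
#' mixture of reference profiles, builds mutation records with contexts
#' (half presented on the purine strand, exercising pyrimidine
#' normalization downstream), and assigns transcriptional strand labels:
#' mutations attributed to the melphalan-like signature that are C>T in
#' its five characteristic contexts are labeled transcribed with
#' probability \code{r/(1+r)} where r = \code{strand_bias_ratio}; all
#' other mutations are labeled 50/50.
#'
#' @param n_mutations number of mutations (> 0).
#' @param weights named signature weights summing to 1 (names must match
#'   reference rows).
#' @param ref a \code{signature_reference} (default: the toy reference).
#' @param strand_bias_ratio expected transcribed:untranscribed ratio for
#'   melphalan-context C>T mutations of the melphalan signature
#'   (default 2; 1 = no bias).
#' @param sample_id label for the catalog.
#' @param seed optional seed.
#' @return list with \code{catalog} (an \code{sbs_catalog}),
#'   \code{mutations} (data.frame with channel, context, ref, alt,
#'   tx_strand, signature), and \code{truth} (weights, realized
#'   per-signature counts, strand_bias_ratio).
#' @export
simulate_catalog <- function(n_mutations, weights,
                             ref = toy_signature_reference(),
                             strand_bias_ratio = 2,
                             sample_id = "sim", seed = NULL) {
  if (n_mutations <= 0L) stop("n_mutations must be positive")
  if (is.null(names(weights)) || !all(names(weights) %in% rownames(ref))) {
    stop("weights must be named by reference signatures")
  }
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (strand_bias_ratio < 1) stop("strand_bias_ratio must be >= 1")
  with_seed(seed, {
    sig <- sample(names(weights), n_mutations, replace = TRUE,
                  prob = weights)
    channels <- sbs96_channels()
    ch <- vapply(sig, function(s) {
      sample(channels, 1L, prob = ref[s, ])
    }, character(1))
    muts <- mutation_records_from_channels(ch, sample_id)
    muts$signature <- sig
    mm1 <- sig == "SBS-MM1" & ch %in% mm1_channels()
    p_tr <- ifelse(mm1, strand_bias_ratio / (1 + strand_bias_ratio), 0.5)
    muts$tx_strand <- ifelse(stats::runif(n_mutations) < p_tr,
                             "transcribed", "untranscribed")
    list(catalog = build_catalog(muts, sample_id = sample_id),
         mutations = muts,
         truth = list(weights = weights,
                      realized = table(factor(sig, levels = rownames(ref))),
                      strand_bias_ratio = strand_bias_ratio))
  })
}

# Expand channel labels into mutation records; about half are emitted in
# the purine-strand representation so channel normalization is exercised.
mutation_records_from_channels <- function(ch, sample_id,
                                           chrom = "sim1") {
  n <- length(ch)
  ref <- substr(ch, 3, 3)
  alt <- substr(ch, 5, 5)
  context <- paste0(substr(ch, 1, 1), ref, substr(ch, 7, 7))
  flip <- stats::runif(n) < 0.5
  ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  context[flip] <- revcomp(context[flip])
  data.frame(
    sample_id = sample_id, chrom = chrom,
    pos = sample.int(10000000L, n),
    ref = ref, alt = alt,
    alt_reads = 30L, total_reads = 60L, vaf = 0.5,
    context = context, stringsAsFactors = FALSE)
}

#' Tabulate stranded channel counts from labeled mutations
#'
#' Counts mutations per (channel, strand) from a mutation table that
#' already carries \code{tx_strand} labels (e.g. simulator output), as
#' opposed to [stranded_counts()] which derives the labels from
#' transcript intervals. Intergenic records are excluded.
#'
#' @param muts mutation data.frame with \code{ref}, \code{alt},
#'   \code{context}, \code{tx_strand}.
#' @return a \code{stranded_counts} matrix.
#' @export
tabulate_stranded <- function(muts) {
  channels <- sbs96_channels()
  keep <- !is.na(muts$tx_strand) &
    muts$tx_strand %in% c("transcribed", "untranscribed") &
    !is.na(muts$context) & !grepl("[^ACGT]", muts$context)
  out <- matrix(0L, 96, 2,
                dimnames = list(channels,
                                c("transcribed", "untranscribed")))
  if (any(keep)) {
    ch <- channel_of(muts$ref[keep], muts$alt[keep], muts$context[keep])
    tab <- table(factor(ch, levels = channels),
                 factor(muts$tx_strand[keep],
                        levels = c("transcribed", "untranscribed")))
    out[] <- as.integer(tab)
  }
  structure(out, class = "stranded_counts",
            n_intergenic = sum(is.na(muts$tx_strand) |
                                 muts$tx_strand == "intergenic"),
            n_ambiguous = 0L)
}

#' Default cluster layouts per evolution scenario
#'
#' Each layout row is (ccf_early, ccf_late, fraction of variants):
#' stable keeps a clonal and a subclonal population unchanged; linear
#' adds an emerging subclone on a retained clonal backbone; differential
#' swaps dominance between two subclones under a retained backbone.
#'
#' @param scenario "stable", "linear" or "differential".
#' @return data.frame with \code{ccf_early}, \code{ccf_late},
#'   \code{fraction}.
#' @export
default_layout <- function(scenario = c("stable", "linear",
                                        "differential")) {
  scenario <- match.arg(scenario)
  switch(scenario,
    stable = data.frame(ccf_early = c(1, 0.4),
                        ccf_late = c(1, 0.4),
                        fraction = c(0.7, 0.3)),
    linear = data.frame(ccf_early = c(1, 0),
                        ccf_late = c(1, 0.45),
                        fraction = c(0.65, 0.35)),
    differential = data.frame(ccf_early = c(1, 0.75, 0),
                              ccf_late = c(1, 0.05, 0.8),
                              fraction = c(0.4, 0.3, 0.3)))
}

validate_layout <- function(layout, scenario, tau_shift = 0.3,
                            tau_new = 0.25, tau_minor = 0.1) {
  if (abs(sum(layout$fraction) - 1) > 1e-8) {
    stop("layout fractions must sum to 1")
  }
  sol <- list(clusters = data.frame(mean_ccf_early = layout$ccf_early,
                                    mean_ccf_late = layout$ccf_late))
  implied <- as.character(classify_evolution(
    sol, tau_shift = tau_shift, tau_new = tau_new,
    tau_minor = tau_minor)$pattern)
  if (implied != scenario) {
    stop("layout/scenario mismatch: the planted cluster means classify ",
         "as '", implied, "', not '", scenario, "'")
  }
  invisible(layout)
}

#' Simulate a paired early/late variant set under an evolution scenario
#'
#' Plants cluster CCFs per the layout, back-computes expected VAFs
#' through the CCF transform (diploid segments, multiplicity 1), and adds
#' binomial read noise at Poisson-distributed depth. A variant is
#' detected in a sample when it has at least \code{min_alt} alternate
#' reads; the per-sample mutation tables contain detected variants only.
#' Channels/contexts are drawn from a signature mixture so the same
#' variants feed catalog construction: variants present early draw from
#' \code{sig_weights_early}, variants private to the late sample from
#' \code{sig_weights_late} (which is how a therapy-induced signature
#' enters late samples only). RAS hotspot labels are planted per
#' scenario: a differential pair with \code{ras_shift = TRUE} places one
#' RAS mutation in a falling cluster and a different one in a rising
#' cluster; otherwise a persistent RAS mutation rides the clonal
#' backbone.
#'
#' @param scenario "stable", "linear" or "differential".
#' @param n_variants number of union variants (default 200).
#' @param layout cluster layout (default: [default_layout()]).
#' @param depth mean sequencing depth (Poisson; default 100).
#' @param purity tumor purity, recycled to (early, late)
#'   (default 0.95).
#' @param ras_shift plant a RAS dominance shift (only valid for
#'   differential; default TRUE for differential).
#' @param sig_weights_early,sig_weights_late signature mixtures for
#'   pre-existing and newly acquired variants.
#' @param ref signature reference.
#' @param strand_bias_ratio passed to the strand labeler.
#' @param patient_id label.
#' @param min_alt detection threshold on alternate reads (default 2).
#' @param seed optional seed.
#' @return list with \code{muts_early}, \code{muts_late} (detected
#'   variants, mutation-table format plus \code{gene},
#'   \code{protein_change}), \code{variants} (union table with true
#'   CCFs, cluster index, signature), \code{segments}, \code{purity},
#'   and \code{truth} (scenario, layout, ras_shift flag).
#' @export
simulate_pair <- function(scenario = c("stable", "linear", "differential"),
                          n_variants = 200L,
                          layout = default_layout(scenario),
                          depth = 100, purity = 0.95,
                          ras_shift = identical(scenario, "differential"),
                          sig_weights_early = c(SIG1 = 0.4, SIG5 = 0.6),
                          sig_weights_late = c(SIG1 = 0.4, SIG5 = 0.6),
                          ref = toy_signature_reference(),
                          strand_bias_ratio = 2,
                          patient_id = "simP", min_alt = 2L,
                          seed = NULL) {
  scenario <- match.arg(scenario)
  validate_layout(layout, scenario)
  purity <- rep_len(purity, 2L)
  if (ras_shift && scenario != "differential") {
    stop("a planted RAS shift requires the differential scenario ",
         "(needs a falling and a rising cluster)")
  }
  with_seed(seed, {
    k <- nrow(layout)
    cl <- sample.int(k, n_variants, replace = TRUE,
                     prob = layout$fraction)
    ccf_e <- layout$ccf_early[cl]
    ccf_l <- layout$ccf_late[cl]
    new_variant <- layout$ccf_early[cl] < 1e-12
    draw_sig <- function(n, w) {
      if (n == 0L) return(character(0))
      sample(names(w), n, replace = TRUE, prob = w)
    }
    sig <- character(n_variants)
    sig[!new_variant] <- draw_sig(sum(!new_variant), sig_weights_early)
    sig[new_variant] <- draw_sig(sum(new_variant), sig_weights_late)
    channels <- sbs96_channels()
    ch <- vapply(sig, function(s) sample(channels, 1L, prob = ref[s, ]),
                 character(1))
    base <- mutation_records_from_channels(ch, sample_id = NA_character_)
    base$pos <- sample.int(10000000L, n_variants)  # unique keys
    base$gene <- NA_character_
    base$protein_change <- NA_character_
    mm1 <- sig == "SBS-MM1" & ch %in% mm1_channels()
    p_tr <- ifelse(mm1, strand_bias_ratio / (1 + strand_bias_ratio), 0.5)
    base$tx_strand <- ifelse(stats::runif(n_variants) < p_tr,
                             "transcribed", "untranscribed")
    # RAS hotspot labels
    if (ras_shift) {
      delta <- layout$ccf_late - layout$ccf_early
      fall_cl <- which.min(delta)
      rise_cl <- which.max(delta)
      i_fall <- which(cl == fall_cl)[1]
      i_rise <- which(cl == rise_cl)[1]
      base$gene[i_fall] <- "KRAS"; base$protein_change[i_fall] <- "G12D"
      base$gene[i_rise] <- "NRAS"; base$protein_change[i_rise] <- "Q61K"
    } else {
      backbone <- which.max(pmin(layout$ccf_early, layout$ccf_late))
      i_ras <- which(cl == backbone)[1]
      if (!is.na(i_ras)) {
        base$gene[i_ras] <- "KRAS"; base$protein_change[i_ras] <- "G12D"
      }
    }
    sample_reads <- function(ccf, pur) {
      vaf <- ccf * pur * 1 / (pur * 2 + (1 - pur) * 2)
      if (!is.finite(depth)) {  # noiseless limit
        tot <- rep(10000000L, n_variants)
        alt <- round(vaf * tot)
      } else {
        tot <- pmax(stats::rpois(n_variants, depth), 1L)
        alt <- stats::rbinom(n_variants, tot, vaf)
      }
      list(alt = alt, tot = tot)
    }
    re <- sample_reads(ccf_e, purity[1])
    rl <- sample_reads(ccf_l, purity[2])
    mk_sample <- function(reads, tp) {
      det <- reads$alt >= min_alt
      df <- base[det, , drop = FALSE]
      df$sample_id <- paste0(patient_id, "_", tp)
      df$alt_reads <- reads$alt[det]
      df$total_reads <- reads$tot[det]
      df$vaf <- df$alt_reads / df$total_reads
      df$patient_id <- patient_id
      rownames(df) <- NULL
      df
    }
    variants <- base
    variants$cluster <- cl
    variants$ccf_early <- ccf_e
    variants$ccf_late <- ccf_l
    variants$signature <- sig
    segments <- data.frame(chrom = "sim1", start = 1L, end = 10000001L,
                           total_cn = 2L, minor_cn = 1L)
    list(
      muts_early = mk_sample(re, "early"),
      muts_late = mk_sample(rl, "late"),
      variants = variants,
      segments = segments,
      purity = c(early = purity[1], late = purity[2]),
      truth = list(patient_id = patient_id, scenario = scenario,
                   layout = layout, ras_shift = ras_shift))
  })
}

#' Simulate paired TPM matrices with planted panel shifts
#'
#' Background expression follows a heavy-tailed paired model on the
#' log2(TPM + 1) scale: per-gene baselines drawn N(2, 1), a per-patient
#' per-gene effect of sd \code{patient_sd} shared by the patient's early
#' and late samples (between-patient biological variation), and
#' within-pair noise of sd \code{noise_sd} (sampling/technical
#' variation, small relative to \code{patient_sd} so that a patient with
#' no planted effect is transcriptionally stable). In late samples every
#' gene of a named panel is additionally shifted by the panel's effect
#' (log2 units; the default 0.5 is one between-patient sd). CGA-panel
#' genes are instead modeled as off (TPM ~ 0) and switched on (TPM
#' around \code{cga_on_tpm}) in \code{n_cga_on} genes of the late sample
#' for a fraction \code{cga_on_fraction} of patients.
#'
#' @param n_patients number of early/late pairs.
#' @param panels named list of gene panels present in the matrix.
#' @param effects named numeric vector of late-sample shifts (log2
#'   units) per panel name; panels not named get 0.
#' @param patient_sd sd of the pair-shared per-patient gene effect
#'   (default 0.5).
#' @param cga_panel name of the panel treated as CGAs (default
#'   "CGA_27" when present).
#' @param cga_on_fraction fraction of patients whose late sample
#'   switches CGAs on (default 0.5).
#' @param n_cga_on number of CGA genes switched on (default 4).
#' @param cga_on_tpm TPM level of switched-on CGAs (default 8).
#' @param n_background additional unaffected background genes
#'   (default 400).
#' @param noise_sd within-pair per-sample noise sd on the log2 scale
#'   (default 0.02).
#' @param seed optional seed.
#' @return list with \code{tpm} (genes x samples, columns
#'   "P<i>_early"/"P<i>_late"), \code{pairs} (data.frame patient_id,
#'   early, late), and \code{truth} (effects, cga_on per patient).
#' @export
simulate_expression <- function(n_patients = 12L,
                                panels = builtin_panels(),
                                effects = c(PI_11 = 0.5),
                                cga_panel = intersect("CGA_27",
                                                      names(panels)),
                                cga_on_fraction = 0.5,
                                n_cga_on = 4L, cga_on_tpm = 8,
                                n_background = 400L, patient_sd = 0.5,
                                noise_sd = 0.02, seed = NULL) {
  with_seed(seed, {
    bg_genes <- sprintf("BG%04d", seq_len(n_background))
    panel_genes <- unique(unlist(panels, use.names = FALSE))
    genes <- c(panel_genes, bg_genes)
    cga_genes <- if (length(cga_panel)) panels[[cga_panel]] else character()
    samples <- as.vector(rbind(sprintf("P%02d_early", seq_len(n_patients)),
                               sprintf("P%02d_late", seq_len(n_patients))))
    baseline <- stats::rnorm(length(genes), mean = 2, sd = 1)
    names(baseline) <- genes
    baseline[genes %in% cga_genes] <- 0
    patient_fx <- matrix(stats::rnorm(length(genes) * n_patients,
                                      mean = 0, sd = patient_sd),
                         nrow = length(genes))
    log2m <- matrix(stats::rnorm(length(genes) * length(samples),
                                 mean = 0, sd = noise_sd),
                    nrow = length(genes),
                    dimnames = list(genes, samples))
    log2m <- log2m + baseline +
      patient_fx[, rep(seq_len(n_patients), each = 2)]
    late_cols <- grep("_late$", samples)
    for (p in setdiff(names(effects), cga_panel)) {
      if (!p %in% names(panels)) next
      rows <- genes %in% panels[[p]]
      log2m[rows, late_cols] <- log2m[rows, late_cols] + effects[[p]]
    }
    cga_on <- rep(FALSE, n_patients)
    if (length(cga_genes) && cga_on_fraction > 0) {
      n_on <- round(cga_on_fraction * n_patients)
      cga_on[seq_len(n_on)] <- TRUE
      on_genes <- utils::head(intersect(genes, cga_genes), n_cga_on)
      for (i in which(cga_on)) {
        log2m[on_genes, sprintf("P%02d_late", i)] <- log2(cga_on_tpm + 1)
      }
    }
    tpm <- pmax(2^log2m - 1, 0)
    pairs <- data.frame(patient_id = sprintf("P%02d", seq_len(n_patients)),
                        early = sprintf("P%02d_early", seq_len(n_patients)),
                        late = sprintf("P%02d_late", seq_len(n_patients)),
                        stringsAsFactors = FALSE)
    list(tpm = tpm, pairs = pairs,
         truth = list(effects = effects, cga_on = cga_on,
                      patient_sd = patient_sd, noise_sd = noise_sd))
  })
}

#' Simulate a full cohort and write it to disk
#'
#' Generates a paired cohort in the file formats the pipeline reads:
#' per-sample mutation TSVs, a segments TSV, a samples table with purity
#' and timepoints, a TPM matrix, a panels GMT and a ground-truth JSON.
#' Scenario counts default to the cohort-shaped proportions
#' (differential-heavy); melphalan exposure groups are assigned
#' round-robin and the melphalan-like signature enters the newly
#' acquired mutations of exposed patients.
#'
#' @param out_dir output directory (created).
#' @param n_patients cohort size (default 12).
#' @param scenario_counts named counts over
#'   stable/linear/differential; default approximates a 58/23/19
#'   differential/linear/stable split.
#' @param n_mut_early median-67-like early mutation count generator:
#'   a function of (n) returning integer counts, or a fixed integer.
#' @param mm1_weight melphalan-signature weight among newly acquired
#'   mutations of melphalan-exposed (HDM) patients (default 0.35).
#' @param depth,noise_sd,effects forwarded to the stage simulators.
#' @param seed seed for the whole cohort (required for
#'   reproducibility).
#' @return invisibly, the ground-truth list (also written as JSON).
#' @export
simulate_cohort <- function(out_dir, n_patients = 12L,
                            scenario_counts = c(differential = 7L,
                                                linear = 3L, stable = 2L),
                            n_mut_early = NULL, mm1_weight = 0.35,
                            depth = 100, noise_sd = 0.02,
                            effects = c(PI_11 = 0.5), seed = 1L) {
  stopifnot(sum(scenario_counts) == n_patients)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panels <- builtin_panels()
  scen <- rep(names(scenario_counts), scenario_counts)
  groups <- rep(c("HDM", "LDM", "noM"), length.out = n_patients)
  truth <- list(patients = list())
  with_seed(seed, {
    n_early <- if (is.null(n_mut_early)) {
      pmax(round(stats::rlnorm(n_patients, log(67), 0.35)), 20L)
    } else {
      rep_len(n_mut_early, n_patients)
    }
    sample_rows <- list()
    for (i in seq_len(n_patients)) {
      pid <- sprintf("P%02d", i)
      layout <- default_layout(scen[i])
      f_early <- sum(layout$fraction[layout$ccf_early > 0])
      n_var <- max(round(n_early[i] / f_early), 20L)
      late_w <- if (groups[i] == "HDM") {
        c(SIG1 = 0.3 * (1 - mm1_weight) / 0.9,
          SIG5 = 0.6 * (1 - mm1_weight) / 0.9,
          `SBS-MM1` = mm1_weight)
      } else {
        c(SIG1 = 1 / 3, SIG5 = 2 / 3)
      }
      late_w <- late_w / sum(late_w)
      pair <- simulate_pair(
        scen[i], n_variants = n_var, depth = depth,
        ras_shift = scen[i] == "differential",
        sig_weights_late = late_w, patient_id = pid,
        seed = NULL)
      utils::write.table(pair$muts_early,
                         file.path(out_dir, paste0(pid, "_early.muts.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(pair$muts_late,
                         file.path(out_dir, paste0(pid, "_late.muts.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(pair$segments,
                         file.path(out_dir, paste0(pid, ".segments.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sample_rows[[length(sample_rows) + 1L]] <- data.frame(
        patient_id = pid,
        sample_id = paste0(pid, c("_early", "_late")),
        timepoint = c("early", "late"),
        purity = unname(pair$purity),
        treatment_group = groups[i],
        muts_file = paste0(pid, c("_early", "_late"), ".muts.tsv"),
        segments_file = paste0(pid, ".segments.tsv"),
        stringsAsFactors = FALSE)
      truth$patients[[pid]] <- list(
        scenario = scen[i], ras_shift = scen[i] == "differential",
        treatment_group = groups[i],
        n_early_detected = nrow(pair$muts_early),
        n_late_detected = nrow(pair$muts_late),
        mm1_in_new = groups[i] == "HDM")
    }
    expr <- simulate_expression(n_patients = n_patients, panels = panels,
                                effects = effects, noise_sd = noise_sd,
                                seed = NULL)
    write_expression(expr$tpm, file.path(out_dir, "tpm.tsv"))
    write_gmt(panels, file.path(out_dir, "panels.gmt"))
    utils::write.table(do.call(rbind, sample_rows),
                       file.path(out_dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth$expression <- expr$truth
    truth$seed <- seed
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(truth)
}
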