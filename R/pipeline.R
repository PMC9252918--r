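#' Purity-based sample QC filter
#'
#' Retains samples with tumor purity at or above the inclusion bound
#' (default 0.80, inclusive). Patients left with fewer than two retained
#' samples are flagged as dropped from paired analyses but keep their
#' per-sample outputs.
#'
#' @param samples data.frame with \code{patient_id}, \code{sample_id},
#'   \code{purity}.
#' @param min_purity inclusion bound (default 0.8).
#' @return list with \code{retained} (data.frame), \code{excluded}
#'   (data.frame with \code{reason}), and \code{dropped_patients}
#'   (patients without a retained pair).
#' @export
qc_filter <- function(samples, min_purity = 0.8) {
  if (is.null(samples$purity) || any(is.na(samples$purity))) {
    stop("every sample needs a purity value")
  }
  keep <- samples$purity >= min_purity
  excluded <- samples[!keep, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reason <- sprintf("purity %.2f below inclusion bound %.2f",
                               excluded$purity, min_purity)
  } else {
    excluded$reason <- character(0)
  }
  retained <- samples[keep, , drop = FALSE]
  per_patient <- table(retained$patient_id)
  dropped <- names(per_patient)[per_patient < 2L]
  dropped <- union(dropped,
                   setdiff(samples$patient_id, retained$patient_id))
  list(retained = retained, excluded = excluded,
       dropped_patients = dropped)
}

#' Mutation load per sample and paired change
#'
#' Counts exonic SNVs per sample (the input tables are already
#' exome-restricted) with an optional restriction by a consequence
#' column, and reports the paired delta and fold change.
#'
#' @param muts_by_sample named list of mutation data.frames.
#' @param pairs optional data.frame with \code{patient_id},
#'   \code{early}, \code{late} sample ids.
#' @param nonsynonymous_only restrict to rows whose \code{consequence}
#'   column is "nonsynonymous" (default FALSE).
#' @return list with \code{per_sample} (named counts) and \code{paired}
#'   (data.frame with delta and fold) when pairs are given.
#' @export
mutation_load <- function(muts_by_sample, pairs = NULL,
                          nonsynonymous_only = FALSE) {
  counts <- vapply(muts_by_sample, function(df) {
    if (nonsynonymous_only && !is.null(df$consequence)) {
      df <- df[df$consequence == "nonsynonymous", , drop = FALSE]
    }
    nrow(df)
  }, integer(1))
  out <- list(per_sample = counts)
  if (!is.null(pairs)) {
    out$paired <- data.frame(
      patient_id = pairs$patient_id,
      n_early = counts[pairs$early],
      n_late = counts[pairs$late],
      delta = counts[pairs$late] - counts[pairs$early],
      fold = counts[pairs$late] / counts[pairs$early],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}

#' Default pipeline configuration
#'
#' @param input_dir directory holding a simulated or prepared cohort
#'   (samples.tsv, per-sample mutation TSVs, segments, tpm.tsv,
#'   panels.gmt).
#' @param out_dir output directory.
#' @param seed master seed; all stage randomness (bootstraps, cluster
#'   restarts) flows from it.
#' @return named list of configuration values.
#' @export
default_config <- function(input_dir, out_dir, seed = 1L) {
  list(
    input_dir = input_dir,
    out_dir = out_dir,
    seed = seed,
    min_purity = 0.8,
    n_bootstrap = 1000L,
    ci_level = 0.95,
    alpha = 0.05,
    tau_shift = 0.3,
    tau_new = 0.25,
    tau_minor = 0.1,
    ccf_cap = 1.5,
    k_max = 6L,
    n_restarts = 10L,
    min_rna_alt = 2L,
    cga_tpm_threshold = 2,
    ssgsea_exponent = 0.25,
    signature_reference = NULL)  # NULL -> toy reference
}

#' Run the full paired-cohort pipeline
#'
#' Orchestrates QC, catalog construction, signature fitting with
#' bootstrap CIs and strand-bias testing, CCF estimation, paired
#' clustering, evolution classification, RAS-shift detection,
#' transcriptomic scoring, and the per-patient report. Deterministic
#' under the configured seed; rerunning with the same configuration
#' produces byte-identical tables. Outputs: \code{exposures.tsv},
#'   \code{sample_scores.tsv}, \code{patient_reports.tsv},
#'   \code{manifest.json} under \code{out_dir}.
#'
#' @param config a list from [default_config()] (possibly edited) or a
#'   path to an equivalent YAML file.
#' @return invisibly, a list with \code{reports} (data.frame),
#'   \code{exposures}, \code{scores}, \code{manifest}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_config(config$input_dir, config$out_dir,
                             config$seed)
  config <- utils::modifyList(defaults, config)
  stopifnot(!is.null(config$input_dir), !is.null(config$out_dir))
  samples_path <- file.path(config$input_dir, "samples.tsv")
  tpm_path <- file.path(config$input_dir, "tpm.tsv")
  panels_path <- file.path(config$input_dir, "panels.gmt")
  for (p in c(samples_path, tpm_path, panels_path)) {
    if (!file.exists(p)) stop("missing input file: ", p)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  qc <- qc_filter(samples, min_purity = config$min_purity)
  retained <- qc$retained
  ref <- if (is.null(config$signature_reference)) {
    toy_signature_reference()
  } else {
    read_signature_reference(config$signature_reference)
  }

  muts_by_sample <- lapply(seq_len(nrow(retained)), function(i) {
    read_mutations(file.path(config$input_dir, retained$muts_file[i]),
                   sample_id = retained$sample_id[i],
                   patient_id = retained$patient_id[i])
  })
  names(muts_by_sample) <- retained$sample_id

  paired_patients <- setdiff(unique(retained$patient_id),
                             qc$dropped_patients)
  pairs <- do.call(rbind, lapply(paired_patients, function(pid) {
    rows <- retained[retained$patient_id == pid, , drop = FALSE]
    rows <- rows[order(match(rows$timepoint, c("early", "late")),
                       rows$sample_id), , drop = FALSE]
    data.frame(patient_id = pid,
               early = rows$sample_id[1],
               late = rows$sample_id[nrow(rows)],  # latest available
               stringsAsFactors = FALSE)
  }))

  load_res <- mutation_load(muts_by_sample, pairs)

  tpm <- read_expression(tpm_path)
  panels <- read_gmt(panels_path)
  z <- zscore_across_samples(tpm, log_transform = TRUE)
  score_panels <- panels[!names(panels) %in% c("CGA_27")]
  ssg <- ssgsea_matrix(z, score_panels,
                       exponent = config$ssgsea_exponent)
  pi_vals <- proliferation_index(tpm)
  cga_counts <- count_expressed_cgas(
    tpm, tpm_threshold = config$cga_tpm_threshold)
  nfkb <- panel_index(tpm, builtin_panels("NFKB_INDEX"))
  hla1 <- panel_index(tpm, builtin_panels("HLA_I"))
  hla2 <- panel_index(tpm, builtin_panels("HLA_II"))

  exposures <- list()
  reports <- list()
  for (pid in paired_patients) {
    pe <- pairs[pairs$patient_id == pid, ]
    me <- muts_by_sample[[pe$early]]
    ml <- muts_by_sample[[pe$late]]
    seg_file <- retained$segments_file[retained$patient_id == pid][1]
    segments <- utils::read.delim(file.path(config$input_dir, seg_file),
                                  stringsAsFactors = FALSE)
    purity_e <- retained$purity[retained$sample_id == pe$early]
    purity_l <- retained$purity[retained$sample_id == pe$late]

    # signatures per sample; the melphalan signature is judged on the
    # late (post-treatment) sample, where newly acquired mutations live
    cat_e <- build_catalog(me)
    cat_l <- build_catalog(ml)
    expo_e <- as.data.frame(bootstrap_ci(cat_e, ref,
                                         n_bootstrap = config$n_bootstrap,
                                         level = config$ci_level))
    expo_l <- as.data.frame(bootstrap_ci(cat_l, ref,
                                         n_bootstrap = config$n_bootstrap,
                                         level = config$ci_level))
    expo_e$sample_id <- pe$early
    expo_l$sample_id <- pe$late
    expo_df <- rbind(expo_e, expo_l)
    expo_df$patient_id <- pid
    exposures[[pid]] <- expo_df
    mm1 <- expo_l[expo_l$signature == "SBS-MM1", ]

    sb <- if (!is.null(ml$tx_strand)) {
      strand_bias_test(tabulate_stranded(rbind_fill(me, ml)),
                       alpha = config$alpha)
    } else {
      NULL
    }

    # CCF union across timepoints (absent -> 0)
    ce <- compute_ccf(me, segments, purity_e, cap = config$ccf_cap)
    clt <- compute_ccf(ml, segments, purity_l, cap = config$ccf_cap)
    key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
    union_keys <- union(key(ce), key(clt))
    ccf_e <- stats::setNames(rep(0, length(union_keys)), union_keys)
    ccf_l <- ccf_e
    ccf_e[key(ce)] <- ce$ccf
    ccf_l[key(clt)] <- clt$ccf
    sol <- cluster_pair(ccf_e, ccf_l, k_max = config$k_max,
                        n_restarts = config$n_restarts)
    evo <- classify_evolution(sol, tau_shift = config$tau_shift,
                              tau_new = config$tau_new,
                              tau_minor = config$tau_minor,
                              patient_id = pid,
                              pair = c(pe$early, pe$late))

    ras <- detect_ras_shift(
      ras_table(ce, clt, union_keys),
      tau_shift = config$tau_shift, tau_new = config$tau_new,
      tau_minor = config$tau_minor)

    cn_flags <- cn_event_flags(segments)

    expr_ok <- all(c(pe$early, pe$late) %in% colnames(tpm))
    if (expr_ok) {
      pi_chg <- classify_pi_change(pi_vals[pe$early], pi_vals[pe$late])
      cga_chg <- classify_cga_change(cga_counts[pe$early],
                                     cga_counts[pe$late])
      ssg_delta <- ssg[, pe$late] - ssg[, pe$early]
    }
    reports[[pid]] <- data.frame(
      patient_id = pid,
      early_sample = pe$early, late_sample = pe$late,
      evolution = as.character(evo$pattern),
      n_clusters = sol$k,
      ras_shift = ras$shift,
      mm1_weight = mm1$weight, mm1_present = mm1$present,
      strand_bias_p = if (is.null(sb)) NA_real_ else sb$p_value,
      strand_bias_significant = if (is.null(sb)) NA else sb$significant,
      n_muts_early = nrow(me), n_muts_late = nrow(ml),
      mut_load_delta = nrow(ml) - nrow(me),
      gain1q = cn_flags[["gain1q"]], amp1q21 = cn_flags[["amp1q21"]],
      del17p = cn_flags[["del17p"]],
      pi_early = if (expr_ok) unname(pi_chg$early) else NA_real_,
      pi_late = if (expr_ok) unname(pi_chg$late) else NA_real_,
      pi_class = if (expr_ok) as.character(pi_chg$class) else
        "no_expression_data",
      cga_early = if (expr_ok) unname(cga_chg$early) else NA_integer_,
      cga_late = if (expr_ok) unname(cga_chg$late) else NA_integer_,
      cga_class = if (expr_ok) as.character(cga_chg$class) else
        "no_expression_data",
      nfkb_delta = if (expr_ok) unname(nfkb[pe$late] - nfkb[pe$early])
        else NA_real_,
      stringsAsFactors = FALSE)
  }
  reports <- do.call(rbind, reports)
  rownames(reports) <- NULL
  exposures <- do.call(rbind, exposures)
  rownames(exposures) <- NULL

  scores <- data.frame(
    sample_id = colnames(tpm),
    PI = unname(pi_vals[colnames(tpm)]),
    CGA_count = unname(cga_counts[colnames(tpm)]),
    NFKB_index = unname(nfkb[colnames(tpm)]),
    HLA_I = unname(hla1[colnames(tpm)]),
    HLA_II = unname(hla2[colnames(tpm)]),
    t(ssg)[colnames(tpm), , drop = FALSE],
    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(scores) <- NULL

  manifest <- list(
    package = "mmclonetrack",
    version = as.character(utils::packageVersion("mmclonetrack")),
    seed = config$seed,
    config = config[setdiff(names(config), c("input_dir", "out_dir"))],
    n_samples_in = nrow(samples),
    n_samples_retained = nrow(retained),
    excluded = qc$excluded$sample_id,
    dropped_patients = qc$dropped_patients,
    n_patients_paired = length(paired_patients))

  utils::write.table(reports, file.path(config$out_dir,
                                        "patient_reports.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(exposures, file.path(config$out_dir,
                                          "exposures.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(scores, digits = 10),
                     file.path(config$out_dir, "sample_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(reports = reports, exposures = exposures,
                 scores = scores, manifest = manifest, qc = qc))
}

# union RAS CCF table from two computed-CCF tables
ras_table <- function(ce, clt, union_keys) {
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
  gene_of <- c(stats::setNames(ce$gene, key(ce)),
               stats::setNames(clt$gene, key(clt)))
  pc_of <- c(stats::setNames(ce$protein_change, key(ce)),
             stats::setNames(clt$protein_change, key(clt)))
  ras_keys <- union_keys[!is.na(gene_of[union_keys]) &
                           gene_of[union_keys] %in% c("KRAS", "NRAS")]
  if (length(ras_keys) == 0L) return(NULL)
  e_ccf <- stats::setNames(rep(0, length(ras_keys)), ras_keys)
  l_ccf <- e_ccf
  ke <- key(ce); kl <- key(clt)
  e_ccf[intersect(ras_keys, ke)] <-
    ce$ccf[match(intersect(ras_keys, ke), ke)]
  l_ccf[intersect(ras_keys, kl)] <-
    clt$ccf[match(intersect(ras_keys, kl), kl)]
  data.frame(gene = unname(gene_of[ras_keys]),
             protein_change = unname(pc_of[ras_keys]),
             ccf_early = unname(e_ccf), ccf_late = unname(l_ccf),
             stringsAsFactors = FALSE)
}

# rbind tolerating different column sets
rbind_fill <- function(a, b) {
  cols <- union(names(a), names(b))
  for (cc in setdiff(cols, names(a))) a[[cc]] <- NA
  for (cc in setdiff(cols, names(b))) b[[cc]] <- NA
  rbind(a[cols], b[cols])
}
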