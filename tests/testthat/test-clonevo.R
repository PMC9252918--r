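test_that("CCF transform matches the closed-form oracle and is monotone in VAF", {
  expect_equal(ccf_from_vaf(0.5, 1, 2)$ccf, 1)
  expect_equal(ccf_from_vaf(0.5, 1, 2)$multiplicity, 1L)
  expect_equal(ccf_from_vaf(0.25, 1, 2)$ccf, 0.5)
  o <- oracle_ccf(0.3, 0.8, 3)
  got <- ccf_from_vaf(0.3, 0.8, 3)
  expect_equal(got$ccf, o$ccf)
  expect_equal(got$multiplicity, o$multiplicity)
  # grid agreement
  grid <- expand.grid(vaf = c(0.05, 0.15, 0.3, 0.45, 0.6),
                      purity = c(0.6, 0.8, 0.9, 0.95, 1),
                      cn = c(1, 2, 3, 4))
  for (i in seq_len(nrow(grid))) {
    o <- oracle_ccf(grid$vaf[i], grid$purity[i], grid$cn[i])
    got <- ccf_from_vaf(grid$vaf[i], grid$purity[i], grid$cn[i],
                        cap = Inf)
    expect_equal(got$ccf, o$ccf, tolerance = 1e-12)
  }
  # monotone in vaf at fixed multiplicity regime
  v <- seq(0.05, 0.4, by = 0.05)
  cc <- ccf_from_vaf(v, 0.9, 2)
  expect_true(all(diff(cc$ccf[cc$multiplicity == 1]) > 0))
  # cap flag
  expect_true(ccf_from_vaf(0.95, 0.5, 1)$capped)
  expect_error(ccf_from_vaf(0.3, 0, 2), "purity")
})

test_that("segment lookup assigns copy number with diploid fallback", {
  muts <- data.frame(sample_id = "s", chrom = c("1", "1", "2"),
                     pos = c(100L, 900L, 100L), ref = "C", alt = "T",
                     alt_reads = 10L, total_reads = 40L, vaf = 0.25)
  segs <- data.frame(chrom = "1", start = 1L, end = 500L,
                     total_cn = 3L, minor_cn = 1L)
  expect_warning(out <- compute_ccf(muts, segs, purity = 0.9),
                 "not covered")
  expect_identical(out$tumor_cn, c(3L, 2L, 2L))
  expect_identical(out$cn_fallback, c(FALSE, TRUE, TRUE))
  bad <- data.frame(chrom = "1", start = 10L, end = 5L, total_cn = 2L,
                    minor_cn = 1L)
  expect_error(compute_ccf(muts, bad, purity = 0.9), "start")
})

test_that("clustering recovers planted structure and selects k by BIC", {
  set.seed(301)
  # tight single clone
  e <- rnorm(80, 1, 0.01)
  l <- rnorm(80, 1, 0.01)
  expect_identical(cluster_pair(e, l)$k, 1L)
  # two well-separated swapped clusters
  e <- c(rnorm(100, 0.9, 0.05), rnorm(100, 0.1, 0.05))
  l <- c(rnorm(100, 0.1, 0.05), rnorm(100, 0.9, 0.05))
  sol <- cluster_pair(e, l)
  expect_identical(sol$k, 2L)
  mu <- sol$clusters[order(sol$clusters$mean_ccf_early), ]
  expect_lt(abs(mu$mean_ccf_early[1] - 0.1), 0.05)
  expect_lt(abs(mu$mean_ccf_late[1] - 0.9), 0.05)
  expect_lt(abs(mu$mean_ccf_early[2] - 0.9), 0.05)
  # clonal backbone + emerging subclone
  e <- c(rnorm(100, 1, 0.05), rnorm(60, 0, 0.02))
  l <- c(rnorm(100, 1, 0.05), rnorm(60, 0.5, 0.05))
  sol <- cluster_pair(pmax(e, 0), pmax(l, 0))
  expect_identical(sol$k, 2L)
  low <- which.min(sol$clusters$mean_ccf_early)
  expect_lt(abs(sol$clusters$mean_ccf_late[low] - 0.5), 0.07)
  expect_error(cluster_pair(0.5, 0.5), "at least 2")
  expect_warning(cluster_pair(rnorm(5, 1, 0.01), rnorm(5, 1, 0.01)),
                 "degraded")
})

test_that("cluster weights sum to one and every variant is assigned once", {
  set.seed(302)
  e <- c(rnorm(60, 0.9, 0.05), rnorm(60, 0.2, 0.05))
  l <- c(rnorm(60, 0.8, 0.05), rnorm(60, 0.2, 0.05))
  sol <- cluster_pair(e, l)
  expect_equal(sum(sol$clusters$weight), 1, tolerance = 1e-8)
  expect_identical(length(sol$assignments), 120L)
  expect_true(all(sol$assignments %in% seq_len(sol$k)))
  expect_identical(sum(sol$clusters$n_variants), 120L)
})

test_that("evolution classification follows the rule table with total precedence", {
  mk <- function(e, l) list(clusters = data.frame(mean_ccf_early = e,
                                                  mean_ccf_late = l))
  expect_identical(as.character(classify_evolution(mk(1, 1))$pattern),
                   "stable")
  expect_identical(
    as.character(classify_evolution(mk(c(0.8, 0.05),
                                       c(0.05, 0.85)))$pattern),
    "differential")
  expect_identical(
    as.character(classify_evolution(mk(c(1, 0), c(1, 0.4)))$pattern),
    "linear")
  # evidence is nonempty unless stable-with-no-change
  call <- classify_evolution(mk(c(1, 0), c(1, 0.4)))
  expect_gt(length(call$evidence), 0)
  # random grid agreement with the independent rule oracle
  set.seed(303)
  for (i in 1:300) {
    k <- sample(1:4, 1)
    e <- round(runif(k, 0, 1.1), 2)
    l <- round(runif(k, 0, 1.1), 2)
    expect_identical(as.character(classify_evolution(mk(e, l))$pattern),
                     oracle_pattern(e, l),
                     info = paste("e:", paste(e, collapse = ","),
                                  "l:", paste(l, collapse = ",")))
  }
})

test_that("RAS-shift detection agrees with the rule oracle on a trajectory grid", {
  expect_false(detect_ras_shift(NULL)$shift)
  expect_false(detect_ras_shift(data.frame(gene = character(),
                                           protein_change = character(),
                                           ccf_early = numeric(),
                                           ccf_late = numeric()))$shift)
  tab <- data.frame(gene = c("KRAS", "NRAS"),
                    protein_change = c("G12D", "Q61K"),
                    ccf_early = c(0.8, 0), ccf_late = c(0.05, 0.7))
  expect_true(detect_ras_shift(tab)$shift)
  single <- data.frame(gene = "KRAS", protein_change = "G12D",
                       ccf_early = 0.9, ccf_late = 0.9)
  expect_false(detect_ras_shift(single)$shift)
  # enumerated grid of two-mutation trajectories
  vals <- c(0, 0.05, 0.2, 0.5, 0.9)
  for (e1 in vals) for (l1 in vals) for (e2 in vals) for (l2 in vals) {
    tab <- data.frame(gene = c("KRAS", "NRAS"),
                      protein_change = c("G12D", "Q61K"),
                      ccf_early = c(e1, e2), ccf_late = c(l1, l2))
    expect_identical(detect_ras_shift(tab)$shift,
                     oracle_ras_shift(c(e1, e2), c(l1, l2),
                                      c("a", "b")),
                     info = paste(e1, l1, e2, l2))
  }
})

test_that("expressed-mutation fractions count RNA support correctly", {
  muts <- data.frame(sample_id = "s", chrom = "c", pos = 1:4, ref = "C",
                     alt = "T", alt_reads = 1L, total_reads = 2L,
                     vaf = 0.5, rna_alt_reads = c(0L, 0L, 3L, 5L))
  r <- expressed_fraction(muts, min_rna_alt = 2L)
  expect_equal(r$fraction, 0.5)
  expect_true(r$defined)
  r0 <- expressed_fraction(muts, min_rna_alt = 0L)
  expect_equal(r0$fraction, 1)
  muts$rna_alt_reads <- NA_integer_
  rna <- expressed_fraction(muts)
  expect_false(rna$defined)
  expect_true(is.na(rna$fraction))
})

test_that("copy-number event flags follow the gain/amp/del conventions", {
  segs <- data.frame(chrom = c("1", "17"), start = c(149e6, 1),
                     end = c(156e6, 12e6), total_cn = c(3L, 1L),
                     minor_cn = c(1L, 0L))
  fl <- cn_event_flags(segs)
  expect_true(fl[["gain1q"]])
  expect_false(fl[["amp1q21"]])
  expect_true(fl[["del17p"]])
  segs$total_cn <- c(5L, 2L)
  fl <- cn_event_flags(segs)
  expect_false(fl[["gain1q"]])
  expect_true(fl[["amp1q21"]])
  expect_false(fl[["del17p"]])
})
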