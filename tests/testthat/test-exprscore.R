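test_that("per-gene z-scoring centers, scales, flags flat genes, and is idempotent", {
  m <- matrix(c(1, 2, 3,
                5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  z <- zscore_across_samples(m, log_transform = FALSE)
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))
  expect_equal(unname(z["g2", ]), c(0, 0, 0))
  expect_identical(attr(z, "flat_genes"), "g2")
  z2 <- zscore_across_samples(z, log_transform = FALSE)
  expect_equal(unname(z2["g1", ]), unname(z["g1", ]), tolerance = 1e-9)
  expect_error(zscore_across_samples(m[, 1, drop = FALSE]),
               ">= 2 samples")
})

test_that("ssGSEA equals the brute-force oracle on random matrices", {
  set.seed(401)
  for (rep in 1:25) {
    genes <- sprintf("g%02d", 1:20)
    z <- matrix(rnorm(20 * 4), nrow = 20,
                dimnames = list(genes, paste0("s", 1:4)))
    set <- sample(genes, sample(2:8, 1))
    for (expo in c(0, 0.25, 1)) {
      got <- ssgsea_score(z, set, exponent = expo)
      want <- vapply(1:4, function(j) {
        oracle_ssgsea(z[, j], genes, set, expo)
      }, numeric(1))
      expect_equal(unname(got), want, tolerance = 1e-9)
    }
  }
})

test_that("rank-only ssGSEA is invariant to monotone transforms and rises under rank promotion", {
  set.seed(402)
  genes <- sprintf("g%02d", 1:20)
  z <- matrix(rnorm(40), nrow = 20, dimnames = list(genes, c("a", "b")))
  set <- c("g03", "g07", "g11")
  s1 <- ssgsea_score(z, set, exponent = 0)
  s2 <- ssgsea_score(sign(z) * abs(z)^3, set, exponent = 0)
  expect_equal(s1, s2, tolerance = 1e-9)
  # moving set members to the top strictly increases the score
  zz <- z
  zz[set, "a"] <- max(z[, "a"]) + 1:3
  expect_gt(ssgsea_score(zz, set, exponent = 0)[["a"]], s1[["a"]])
  # sample order permutations leave per-sample scores unchanged
  perm <- ssgsea_score(z[, c("b", "a")], set, exponent = 0.25)
  orig <- ssgsea_score(z, set, exponent = 0.25)
  expect_equal(perm[["a"]], orig[["a"]], tolerance = 1e-12)
  expect_error(ssgsea_score(z, c("nope1", "nope2")), "no gene")
  expect_error(ssgsea_score(z, genes), "complement")
})

test_that("proliferation index is a centered sum over the panel", {
  pi_genes <- builtin_panels("PI_11")
  set.seed(403)
  n_s <- 6
  tpm <- matrix(runif(15 * n_s, 1, 100), nrow = 15,
                dimnames = list(c(pi_genes[1:11],
                                  paste0("bg", 1:4)),
                                paste0("s", 1:n_s)))
  pi <- proliferation_index(tpm)
  expect_equal(sum(pi), 0, tolerance = 1e-9)  # column sums of z rows
  # one sample at +1 sd for every panel gene scores 11 in sum mode
  z <- zscore_across_samples(tpm)
  shifted <- log2(tpm + 1)
  mu <- rowMeans(shifted)
  sdv <- apply(shifted, 1, sd)
  tpm2 <- cbind(tpm, target = 2^(mu + sdv) - 1)
  pi2 <- proliferation_index(tpm2)
  # after adding the target column the cohort stats shift; check ordering
  expect_identical(names(which.max(pi2)), "target")
  expect_error(proliferation_index(tpm[6:15, ]), "too few")
  pim <- proliferation_index(tpm, aggregate = "mean")
  expect_equal(as.numeric(pim), as.numeric(pi) / 11, tolerance = 1e-9)
})

test_that("PI change classes reproduce the threshold rule exactly", {
  grid <- c(-0.41, -0.4, 0.4, 0.41, 1.0, 1.01)
  got <- as.character(classify_pi_change(rep(0, 6), grid)$class)
  expect_identical(got, c("decrease", "no_change", "no_change",
                          "increase", "increase", "high_increase"))
  # partition: every delta maps to exactly one class
  set.seed(404)
  deltas <- runif(200, -3, 3)
  cls <- classify_pi_change(rep(0, 200), deltas)$class
  expect_false(any(is.na(cls)))
})

test_that("CGA counting uses a strict TPM threshold and the >=3 increase rule", {
  tpm <- matrix(c(1.9, 2.0, 2.1, 50), ncol = 1,
                dimnames = list(c("MAGEA1", "MAGEA3", "MAGEB1", "CTAG2"),
                                "s1"))
  expect_identical(unname(count_expressed_cgas(tpm)), 2L)
  expect_identical(unname(count_expressed_cgas(tpm * 0)), 0L)
  chg <- classify_cga_change(4L, 7L)
  expect_identical(as.character(chg$class), "increased")
  expect_identical(as.character(classify_cga_change(4L, 6L)$class),
                   "no_change")
  expect_identical(as.character(classify_cga_change(7L, 4L)$class),
                   "decreased")
  cls <- classify_cga_change(rep(5L, 21), 0:20)$class
  expect_false(any(is.na(cls)))
})

test_that("panel indices are z-score means with the mean-zero identity", {
  set.seed(405)
  tpm <- matrix(runif(8 * 5, 1, 50), nrow = 8,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  z <- zscore_across_samples(tpm)
  one <- panel_index(tpm, "g3")
  expect_equal(unname(one), unname(z["g3", ]), tolerance = 1e-12)
  # mean-zero identity: every panel index sums to zero across samples,
  # because each gene's z-scores do
  iA <- paste0("g", 1:3); iB <- paste0("g", 4:8)
  expect_equal(sum(panel_index(tpm, iA)), 0, tolerance = 1e-9)
  expect_equal(sum(panel_index(tpm, iB)), 0, tolerance = 1e-9)
  expect_error(panel_index(tpm, c("x", "y")), "no panel gene")
})

test_that("fold changes apply the pseudocount and threshold flags", {
  tpm <- matrix(c(10, 15), nrow = 1,
                dimnames = list("XPO1", c("e", "l")))
  fc <- fold_change(tpm, "XPO1", "e", "l", pseudocount = 1)
  expect_equal(fc$fc, 16 / 11)
  expect_false(fc$fc_gt_1_5)
  expect_false(fc$fc_gt_3)
  tpm0 <- matrix(c(0, 0), nrow = 1, dimnames = list("g", c("e", "l")))
  expect_equal(fold_change(tpm0, "g", "e", "l")$fc, 1)
  expect_error(fold_change(tpm, "nope", "e", "l"), "gene")
})

test_that("Spearman panel recovers planted correlations and flags highlights", {
  scores <- data.frame(a = 1:20)
  scores$b <- scores$a^3  # monotone transform
  out <- spearman_panel(scores, list(c("a", "b")))
  expect_equal(out$rho, 1, tolerance = 1e-9)
  expect_true(out$highlighted)
  set.seed(406)
  x <- rnorm(50)
  y <- 0.7 * x + sqrt(1 - 0.49) * rnorm(50)
  out2 <- spearman_panel(data.frame(x = x, y = y), list(c("x", "y")))
  expect_lt(abs(out2$rho - 0.7), 0.15)
  expect_true("p_adj" %in% names(out2))
  short <- data.frame(u = c(1, 2, NA, NA, NA, NA),
                      v = c(2, 1, NA, NA, NA, NA))
  expect_warning(res <- spearman_panel(short, list(c("u", "v"))),
                 "overlapping")
  expect_identical(nrow(res), 0L)
})

test_that("GMT files round-trip and builtin panels load", {
  sets <- list(one = c("A", "B"), two = c("C", "D", "E"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(back$one, sets$one)
  expect_identical(back$two, sets$two)
  panels <- builtin_panels()
  expect_identical(length(builtin_panels("PI_11")), 11L)
  expect_identical(length(builtin_panels("CGA_27")), 27L)
  expect_error(builtin_panels("nope"), "unknown panel")
})
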