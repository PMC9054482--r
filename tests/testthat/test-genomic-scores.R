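test_that("MSI score is the unstable-site fraction with an inclusive cut", {
  calls <- matrix(FALSE, 3, 52,
                  dimnames = list(c("A", "B", "C"), NULL))
  calls["A", 1:21] <- TRUE   # 21/52 = 0.4038 -> positive
  calls["B", 1:20] <- TRUE   # 20/52 = 0.3846 -> negative
  res <- msi_score(calls)
  expect_equal(res$msi_score, c(21 / 52, 20 / 52, 0))
  expect_identical(res$msi_positive, c(TRUE, FALSE, FALSE))

  # ordering invariance and monotonicity in the unstable count
  perm <- calls[, sample(52), drop = FALSE]
  expect_equal(msi_score(perm)$msi_score, res$msi_score)
  s <- sapply(0:52, function(k)
    msi_score(c(rep(TRUE, k), rep(FALSE, 52 - k)))$msi_score)
  expect_true(all(diff(s) > 0))

  # exact boundary 0.4 flips under the strict comparator
  at_cut <- c(rep(TRUE, 2), rep(FALSE, 3))   # score exactly 0.4
  expect_true(msi_score(at_cut)$msi_positive)
  expect_false(msi_score(at_cut,
                         score_thresholds(msi_comparator = ">"))$msi_positive)

  expect_error(msi_score(matrix(logical(0), 1, 0)),
               class = "eogc_validation_error")
})

test_that("TMB counts kept mutations excluding known drivers", {
  v <- make_variants(7, sample_id = "S1",
                     driver = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                                FALSE))
  expect_equal(tmb(v)$tmb, 5L)
  expect_equal(tmb(v[v$is_known_driver, ])$tmb, 0L)
  expect_equal(tmb(v[0, ], sample_ids = "S1")$tmb, 0L)
  # samples absent from the variant table get zero
  res <- tmb(v, sample_ids = c("S1", "S2"))
  expect_equal(res$tmb, c(5L, 0L))
})

test_that("gene CNV calls use the inclusive 0.6 boundary and sign symmetry", {
  expect_equal(call_gene_cnv(c(0.60, -0.59, 0, 0.59, -0.6, 1.3)),
               c("gain", "neutral", "neutral", "neutral", "loss", "gain"))
  expect_error(call_gene_cnv(c(0.1, NA)), class = "eogc_validation_error")
  expect_error(call_gene_cnv(Inf), class = "eogc_validation_error")

  set.seed(1)
  x <- rnorm(200, sd = 0.7)
  flip <- call_gene_cnv(-x)
  orig <- call_gene_cnv(x)
  expect_identical(flip == "gain", orig == "loss")
  expect_identical(flip == "neutral", orig == "neutral")
})

test_that("CIS averages per-autosome abnormal fractions", {
  # chr1: 2 of 4 abnormal (0.5); chr2: 1 of 5 abnormal (0.2) -> CIS 0.35
  l2m <- make_l2m(c(0.5, -0.9, 0.1, 0.0,  0.3, 0, 0, 0, 0.1),
                  chrom = c(rep("1", 4), rep("2", 5)), arm = "q")
  expect_equal(cis(l2m)$cis, 0.35)

  # saturation and the zero case
  expect_equal(cis(make_l2m(rep(1, 6), chrom = rep(c("1", "2"), 3),
                            arm = "q"))$cis, 1)
  expect_equal(cis(make_l2m(rep(0, 6), chrom = rep(c("1", "2"), 3),
                            arm = "q"))$cis, 0)

  # the abnormal test is strict: |log2| exactly 0.2 is not abnormal
  expect_equal(cis(make_l2m(c(0.2, -0.2, 0.2000001),
                            chrom = "1", arm = "q"))$cis, 1 / 3)

  # sex chromosomes never contribute
  with_x <- make_l2m(c(0.5, -0.9, 0.1, 0.0, 0.3, 0, 0, 0, 0.1, 5, -5),
                     chrom = c(rep("1", 4), rep("2", 5), "X", "Y"),
                     arm = "q")
  expect_equal(cis(with_x)$cis, 0.35)
  expect_error(cis(make_l2m(c(1, 2), chrom = c("X", "Y"), arm = "q")),
               class = "eogc_validation_error")

  # chromosome weighting equals the pooled fraction on balanced panels
  set.seed(7)
  m <- matrix(rnorm(40 * 44, sd = 0.3), 40, 44)
  bal <- make_l2m(m, chrom = rep(as.character(1:22), each = 2), arm = "q")
  cw <- cis(bal, score_thresholds(cis_weighting = "chromosome"))$cis
  gw <- cis(bal, score_thresholds(cis_weighting = "gene"))$cis
  expect_equal(cw, gw, tolerance = 1e-12)

  # unbalanced panel: the two weightings disagree as designed
  # chr1: 4/8 abnormal (0.5); chr2: 0/2 -> chromosome mean 0.25, pooled 0.4
  unbal <- make_l2m(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
                    chrom = c(rep("1", 8), "2", "2"), arm = "q")
  expect_equal(cis(unbal)$cis, 0.25)
  expect_equal(cis(unbal, score_thresholds(cis_weighting = "gene"))$cis, 0.4)
})

test_that("arm calls summarize the arm median against the 0.2 cut", {
  l2m <- make_l2m(c(0.3, 0.4, 0.25,  0.3, -0.3,  -0.8),
                  chrom = c("1", "1", "1", "2", "2", "3"),
                  arm = c("p", "p", "p", "q", "q", "p"))
  res <- call_arm_cnv(l2m)
  calls <- setNames(res$call, res$arm)
  expect_equal(calls[["1p"]], "gain")    # median 0.3
  expect_equal(calls[["2q"]], "neutral") # median 0
  expect_equal(calls[["3p"]], "loss")    # single gene -0.8
})

test_that("score assembly merges MSI, TMB and CIS per sample", {
  sim <- simulate_cohort(simulation_config(n_patients = 60, seed = 13))
  kept <- run_filter_cascade(sim$variants, sim$normal_panel)$kept
  sc <- compute_scores(kept, sim$log2, sim$sites)
  expect_equal(nrow(sc), 60)
  expect_identical(sc$sample_id, rownames(sim$log2$log2ratio))
  expect_true(all(sc$cis >= 0 & sc$cis <= 1))
  expect_true(all(sc$tmb >= 0))
  lat <- sim$truth$latent
  expect_true(all(sc$msi_positive[lat$subtype == "MSI"]))
})
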