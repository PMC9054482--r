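test_that("the feature matrix binarizes mutations and calls per patient", {
  ids <- c("P1", "P2", "P3")
  kept <- make_variants(3, sample_id = c("P1", "P1", "P2"),
                        gene = c("CDH1", "CDH1", "TP53"))
  cnv <- data.frame(sample_id = c("P1", "P2"), gene = c("FGFR2", "MYC"),
                    call = c("gain", "loss"), stringsAsFactors = FALSE)
  arm <- data.frame(sample_id = c("P2", "P3", "P3"),
                    arm = c("20q", "20q", "8p"),
                    call = c("gain", "neutral", "loss"),
                    stringsAsFactors = FALSE)
  fm <- make_feature_matrix(kept, cnv, arm, ids)
  expect_setequal(colnames(fm),
                  c("CDH1_mut", "TP53_mut", "FGFR2_gain", "MYC_loss",
                    "20q_arm_gain", "8p_arm_loss"))
  # two CDH1 mutations still yield a single TRUE
  expect_identical(unname(fm[, "CDH1_mut"]), c(TRUE, FALSE, FALSE))
  expect_identical(unname(fm[, "TP53_mut"]), c(FALSE, TRUE, FALSE))
  expect_identical(unname(fm[, "FGFR2_gain"]), c(TRUE, FALSE, FALSE))
  # patient absent from a call table gets FALSE; neutral rows are ignored
  expect_identical(unname(fm[, "20q_arm_gain"]), c(FALSE, TRUE, FALSE))
  expect_identical(unname(fm[, "8p_arm_loss"]), c(FALSE, FALSE, TRUE))
})

test_that("the prevalence filter keeps features above 5% in either group", {
  ag <- factor(rep(c("young", "old"), each = 1000),
               levels = c("young", "old"))
  f <- cbind(
    a = c(rep(TRUE, 51), rep(FALSE, 949), rep(TRUE, 10), rep(FALSE, 990)),
    b = c(rep(TRUE, 50), rep(FALSE, 950), rep(TRUE, 50), rep(FALSE, 950)),
    c = rep(FALSE, 2000)
  )
  res <- prevalence_filter(f, ag)
  expect_identical(res$retained, c(TRUE, FALSE, FALSE))
  expect_equal(res$freq_young, c(0.051, 0.050, 0))
})

test_that("logistic enrichment matches the 2x2 closed form and handles
           degenerate designs", {
  young <- rep(c(TRUE, FALSE), each = 100)
  feature <- c(rep(TRUE, 30), rep(FALSE, 70), rep(TRUE, 10), rep(FALSE, 90))
  res <- logistic_enrichment(feature, young)
  expect_equal(res$odds_ratio, (30 * 90) / (70 * 10), tolerance = 1e-6)
  expect_true(res$converged)
  expect_true(res$ci_low <= res$odds_ratio & res$odds_ratio <= res$ci_high)
  expect_equal(res$freq_young, 0.30)
  expect_equal(res$freq_old, 0.10)

  # null case: equal frequencies -> OR 1, p 1
  null_f <- rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 70, 30, 70))
  res0 <- logistic_enrichment(null_f, young)
  expect_equal(res0$odds_ratio, 1, tolerance = 1e-8)
  expect_equal(res0$p_value, 1, tolerance = 1e-8)

  # sex covariate independent of outcome and feature: reduces to the 2x2
  sex <- rep(c("male", "female"), 100)
  res_sex <- logistic_enrichment(feature, young, sex)
  expect_equal(res_sex$odds_ratio, (30 * 90) / (70 * 10), tolerance = 1e-3)

  # perfect separation flagged, no finite OR
  sep <- logistic_enrichment(young, young)
  expect_false(sep$converged)
  expect_true(is.na(sep$odds_ratio))

  # constant feature: flagged with p = 1 by convention
  const <- logistic_enrichment(rep(TRUE, 200), young)
  expect_false(const$converged)
  expect_equal(const$p_value, 1)

  # constant outcome is an error
  expect_error(logistic_enrichment(feature, rep(TRUE, 200)),
               class = "eogc_validation_error")
})

test_that("BH adjustment matches hand computation and is order-invariant", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "eogc_validation_error")

  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))^2
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm], tolerance = 1e-12)
  }
})

test_that("the Cuzick statistic matches its exact permutation moments", {
  # three singleton groups, strictly increasing values
  tr <- cuzick_trend(c(1.2, 3.4, 5.6),
                     factor(c("a", "b", "c"), levels = c("a", "b", "c")))
  expect_gt(tr$z, 0)
  perm <- trend_perm_dist(c(1, 1, 1))
  # exact one-sided permutation p at the monotone arrangement is 1/6
  expect_equal(mean(perm >= tr$statistic), 1 / 6)
  expect_equal(tr$expectation, mean(perm))
  expect_equal(tr$variance, mean((perm - mean(perm))^2), tolerance = 1e-12)

  # reversing group order negates z
  rev_tr <- cuzick_trend(c(1.2, 3.4, 5.6),
                         factor(c("a", "b", "c"),
                                levels = c("c", "b", "a")))
  expect_equal(rev_tr$z, -tr$z, tolerance = 1e-12)

  # identical values across groups: degenerate, p = 1
  tied <- cuzick_trend(rep(2, 6), factor(rep(c("a", "b", "c"), 2)))
  expect_true(tied$degenerate)
  expect_equal(tied$p_value, 1)

  # tie-corrected variance equals the permutation variance exactly
  set.seed(9)
  for (i in 1:15) {
    ng <- sample(1:3, sample(2:3, 1), replace = TRUE) + 1
    vals <- sample(1:4, sum(ng), replace = TRUE)   # many ties
    g <- factor(rep(letters[seq_along(ng)], ng))
    tr <- cuzick_trend(vals, g)
    if (tr$degenerate) next
    # permutation oracle on midranks
    r <- rank(vals)
    perms <- trend_perm_ranks(r, ng)
    expect_equal(tr$expectation, mean(perms), tolerance = 1e-9)
    expect_equal(tr$variance, mean((perms - mean(perms))^2),
                 tolerance = 1e-9)
  }

  # normal p converges to the permutation p as N grows
  set.seed(4)
  vals <- rnorm(24)
  g <- factor(rep(c("a", "b", "c"), each = 8))
  tr <- cuzick_trend(vals, g)
  r <- rank(vals)
  samp <- replicate(40000, {
    rr <- sample(r)
    sum(rep(1:3, each = 8) * rr)
  })
  p_perm <- mean(abs(samp - mean(samp)) >= abs(tr$statistic - tr$expectation))
  expect_lt(abs(tr$p_value - p_perm), 0.02)
})

test_that("categorical contrasts pick the right test and match the
           hypergeometric oracle", {
  flat <- categorical_contrast(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$method, "chisq")
  expect_equal(flat$p_value, 1)

  tab <- matrix(c(3, 9, 7, 2), 2)     # min expected cell 4.29 -> Fisher
  res <- categorical_contrast(tab)
  expect_equal(res$method, "fisher")
  expect_equal(res$p_value, fisher_oracle_2x2(tab), tolerance = 1e-9)
  # with all expected cells >= 5 the chi-square branch is chosen
  expect_equal(categorical_contrast(matrix(c(12, 3, 5, 14), 2))$method,
               "chisq")

  # expected cell just below 5 forces Fisher even with large totals
  tab2 <- matrix(c(5, 95, 5, 195), 2)
  expect_lt(min(outer(rowSums(tab2), colSums(tab2)) / sum(tab2)), 5)
  expect_equal(categorical_contrast(tab2)$method, "fisher")

  expect_error(categorical_contrast(matrix(0, 2, 2)),
               class = "eogc_validation_error")
})

test_that("instability-versus-age detects a planted old-group shift", {
  set.seed(12)
  n <- 800
  age <- sample(25:85, n, replace = TRUE)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  old <- age >= 45
  scores <- data.frame(
    tmb = rpois(n, 5 + 5 * old),          # +5 shift in the old group
    cis = pmin(1, pmax(0, rnorm(n, 0.1 + 0.1 * old, 0.05))),
    age = age, sex = sex)
  res <- instability_vs_age(scores)
  # enrichment in the old group: OR for young < 1, rising trend with age
  expect_true(all(res$associations$odds_ratio < 1))
  expect_true(all(res$associations$fdr < 0.05))
  expect_true(all(res$trends$z > 0))

  const <- instability_vs_age(data.frame(tmb = 1, cis = 0.1,
                                         age = age, sex = sex))
  expect_false(any(const$associations$converged))
  expect_true(all(const$trends$degenerate))
})

test_that("the association screen flags planted effects with per-class FDR", {
  sim <- simulate_cohort(simulation_config(n_patients = 4000, seed = 77))
  kept <- run_filter_cascade(sim$variants, sim$normal_panel)$kept
  th <- score_thresholds()
  cnv <- cnv_call_table(sim$log2, th)
  arm <- call_arm_cnv(sim$log2, th)
  ids <- sim$clinical$sample_id
  fm <- make_feature_matrix(kept, cnv, arm, ids)
  young <- sim$truth$latent$young
  res <- test_associations(fm, young, sim$clinical$sex)
  expect_true(all(c("mutation", "cnv", "arm") %in% res$class))
  # planted young-enriched mutation recovered with OR > 1 and low FDR
  cdh1 <- res[res$feature == "CDH1_mut", ]
  expect_gt(cdh1$odds_ratio, 1)
  expect_true(cdh1$significant)
  # planted null mutation not significant
  tp53 <- res[res$feature == "TP53_mut", ]
  expect_false(tp53$significant)
})
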