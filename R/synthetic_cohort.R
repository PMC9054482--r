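# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes -- age distribution peaking near 60 with a young (<45)
# group around 18% of patients, sex odds ~1:1 young and ~3:1 old, latent
# EBV/MSI/CIN/GS subtypes driving EBV status, indel-site instability and
# copy-number profiles, and per-feature alteration frequencies with
# planted young-vs-old odds ratios -- so every downstream stage can be
# exercised and calibrated without restricted patient data.

#' Default planted-feature specification
#'
#' One row per alteration feature: the target gene or arm, the alteration
#' class, the baseline old-group frequency and the planted young-vs-old
#' odds ratio. The defaults plant a young-enriched CDH1-like mutation and
#' FGFR2-like copy-number gain, several old-enriched alterations, and
#' null features (OR 1) for calibration.
#'
#' @return `data.frame` with columns `feature`, `target`, `class`,
#'   `freq_old`, `or_young`.
#' @export
default_feature_spec <- function() {
  data.frame(
    feature = c("CDH1_mut", "TP53_mut", "ARID1A_mut", "PIK3CA_mut",
                "FGFR2_gain", "MYC_gain", "CCNE1_gain", "ZNF217_gain",
                "20q_arm_gain", "4q_arm_loss"),
    target = c("CDH1", "TP53", "ARID1A", "PIK3CA",
               "FGFR2", "MYC", "CCNE1", "ZNF217", "20q", "4q"),
    class = c(rep("mutation", 4), rep("cnv_gain", 4),
              "arm_gain", "arm_loss"),
    freq_old = c(0.06, 0.50, 0.20, 0.12, 0.06, 0.10, 0.08, 0.09,
                 0.15, 0.10),
    or_young = c(2.5, 1.0, 1.0, 0.5, 2.0, 0.6, 1.0, 0.6, 0.5, 0.7),
    stringsAsFactors = FALSE
  )
}

# Genomic placement of the named feature genes (cytoband arm level).
FEATURE_GENE_MAP <- data.frame(
  gene = c("CDH1", "TP53", "ARID1A", "PIK3CA", "FGFR2", "MYC", "CCNE1",
           "ZNF217"),
  chrom = c("16", "17", "1", "3", "10", "8", "19", "20"),
  arm = c("q", "p", "p", "q", "q", "q", "q", "q"),
  stringsAsFactors = FALSE
)

# Aging-like default 96-motif profile: C>T substitutions at NpCpG contexts
# dominate, other C>T elevated, flat background elsewhere.
default_signature_probs <- function() {
  lv <- motif_levels()
  w <- rep(1, 96)
  w[grepl("\\[C>T\\]", lv)] <- 3
  w[grepl("\\[C>T\\]G$", lv)] <- 12
  stats::setNames(w / sum(w), lv)
}

#' Simulation configuration
#'
#' Collects and validates every parameter of the synthetic cohort
#' generator. Defaults encode the cohort structure the analysis assumes:
#' ages from a truncated normal peaking at 60 (sd 11, range 20-90) with
#' the young (<45) fraction fixed at 18.25%; male:female odds 1:1 in the
#' young and 3:1 in the old group; subtype prevalences with the CIN share
#' reduced (and GS share correspondingly raised) in young patients;
#' MSI-subtype patients unstable at 60% of indel sites versus 5%
#' otherwise; TMB drawn Poisson with a mild exponential age slope; and a
#' background copy-number "abnormal gene" fraction rising with age so CIS
#' trends upward.
#'
#' @param n_patients Cohort size (>= 0).
#' @param seed Master seed; all tables derive substream seeds from it.
#' @param age_mean,age_sd,age_range Truncated-normal age model (years).
#' @param young_frac Fraction of patients under the age cutoff.
#' @param age_cutoff Young/old age cutoff in years.
#' @param n_missing_age Number of patients whose age is masked to missing.
#' @param male_odds_young,male_odds_old Male:female odds by age group.
#' @param subtype_probs Named 4-simplex over EBV/MSI/CIN/GS (old group).
#' @param cin_young_factor Multiplier on the CIN probability in young
#'   patients; the removed mass moves to GS.
#' @param feature_spec Planted features (see [default_feature_spec()]).
#' @param cnv_noise_sd Gaussian noise sd on log2 depth ratios.
#' @param gain_log2,loss_log2 Planted log2 values for gene gains/losses.
#' @param arm_shift Log2 shift added to every gene on a planted arm.
#' @param cin_abnormal_frac Fraction of eligible genes planted abnormal in
#'   CIN-subtype patients (drives their expected CIS above 0.25).
#' @param bg_instability_slope Per-year increase of the background
#'   abnormal-gene fraction.
#' @param msi_site_rate_pos,msi_site_rate_neg Per-site instability rates
#'   for MSI / non-MSI patients.
#' @param n_sites Indel-site panel size (default 52).
#' @param tmb_base,tmb_age_slope Passenger-mutation Poisson mean at age 60
#'   and exponential slope per decade.
#' @param msi_tmb_mult TMB multiplier for MSI-subtype patients.
#' @param driver_fraction Fraction of passenger mutations flagged as known
#'   drivers.
#' @param signature_probs 96-motif probability vector for SNV contexts.
#' @param n_background_genes Number of background panel genes.
#' @param fodder_n Number of planted filter-fodder variants (variants that
#'   the filter cascade must remove; default 0, so generated variants pass
#'   the keep-rules by construction).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients,
                              seed = 1,
                              age_mean = 60, age_sd = 11,
                              age_range = c(20, 90),
                              young_frac = 0.1825,
                              age_cutoff = 45,
                              n_missing_age = 0,
                              male_odds_young = 1.0,
                              male_odds_old = 3.0,
                              subtype_probs = c(EBV = 0.09, MSI = 0.16,
                                                CIN = 0.45, GS = 0.30),
                              cin_young_factor = 0.6,
                              feature_spec = default_feature_spec(),
                              cnv_noise_sd = 0.1,
                              gain_log2 = 1.0, loss_log2 = -1.0,
                              arm_shift = 0.3,
                              cin_abnormal_frac = 0.45,
                              bg_instability_slope = 0.0015,
                              msi_site_rate_pos = 0.6,
                              msi_site_rate_neg = 0.05,
                              n_sites = 52,
                              tmb_base = 6, tmb_age_slope = 0.2,
                              msi_tmb_mult = 3,
                              driver_fraction = 0.05,
                              signature_probs = default_signature_probs(),
                              n_background_genes = 120,
                              fodder_n = 0) {
  if (n_patients < 0) stop_config("n_patients must be >= 0")
  if (abs(sum(subtype_probs) - 1) > 1e-9)
    stop_config("subtype_probs must sum to 1")
  if (!all(c("EBV", "MSI", "CIN", "GS") %in% names(subtype_probs)))
    stop_config("subtype_probs must be named EBV/MSI/CIN/GS")
  for (p in c(young_frac, msi_site_rate_pos, msi_site_rate_neg,
              driver_fraction))
    if (p < 0 || p >= 1) stop_config("rates must lie in [0, 1)")
  fs <- feature_spec
  if (nrow(fs) > 0) {
    if (any(fs$freq_old <= 0 | fs$freq_old >= 1))
      stop_config("feature baseline frequencies must lie in (0, 1)")
    if (any(fs$or_young <= 0))
      stop_config("feature odds ratios must be positive")
    py <- implied_young_prob(fs$freq_old, fs$or_young)
    if (any(py <= 0 | py >= 1))
      stop_config("implied young-group probability outside (0, 1)")
  }
  if (n_missing_age > n_patients)
    stop_config("n_missing_age exceeds n_patients")
  cfg <- as.list(environment())
  cfg$fs <- cfg$py <- cfg$p <- NULL
  structure(cfg, class = "simulation_config")
}

#' Young-group carrier probability implied by a baseline frequency and OR
#'
#' `p_young = OR * odds_old / (1 + OR * odds_old)` with
#' `odds_old = p_old / (1 - p_old)`.
#'
#' @param freq_old Old-group carrier frequency in (0, 1).
#' @param or_young Young-vs-old odds ratio (> 0).
#' @return Implied young-group carrier probability.
#' @export
implied_young_prob <- function(freq_old, or_young) {
  odds <- or_young * freq_old / (1 - freq_old)
  odds / (1 + odds)
}

# Panel gene map: feature genes at their genomic arms plus background
# genes round-robin over the autosomal arms, plus two X genes (excluded
# from CIS by construction, present to exercise that rule).
build_gene_panel <- function(config) {
  arms <- paste0(rep(as.character(1:22), each = 2), c("p", "q"))
  nbg <- config$n_background_genes
  bg <- data.frame(
    gene = sprintf("BG%03d", seq_len(nbg)),
    chrom = sub("[pq]$", "", rep(arms, length.out = nbg)),
    arm = sub("^[0-9]+", "", rep(arms, length.out = nbg)),
    stringsAsFactors = FALSE
  )
  xg <- data.frame(gene = c("XG1", "XG2"), chrom = "X", arm = c("p", "q"),
                   stringsAsFactors = FALSE)
  gm <- rbind(FEATURE_GENE_MAP, bg, xg)
  gm$pos_base <- seq_len(nrow(gm)) * 1000000L
  gm
}

discrete_truncnorm <- function(n, lo, hi, mean, sd) {
  support <- lo:hi
  w <- stats::dnorm(support, mean, sd)
  sample(support, n, replace = TRUE, prob = w)
}

# Draw (ref, alt, context3) for n SNVs from a 96-motif profile, flipping
# half of them to the purine strand to exercise normalization downstream.
draw_snv_contexts <- function(n, signature_probs) {
  lv <- motif_levels()
  idx <- sample.int(96, n, replace = TRUE, prob = signature_probs)
  mot <- lv[idx]
  ref <- substr(mot, 3, 3)
  alt <- substr(mot, 5, 5)
  ctx <- paste0(substr(mot, 1, 1), ref, substr(mot, 7, 7))
  flip <- stats::runif(n) < 0.5
  if (any(flip)) {
    ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
    alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
    ctx[flip] <- revcomp(ctx[flip])
  }
  data.frame(ref = ref, alt = alt, context3 = ctx, stringsAsFactors = FALSE)
}

make_variant_rows <- function(sample_id, gene, gene_map, contexts,
                              hotspot, driver, min_reads = 6) {
  n <- length(sample_id)
  gi <- match(gene, gene_map$gene)
  total <- sample(200:800, n, replace = TRUE)
  vaf <- stats::runif(n, 0.05, 0.40)
  mutant <- pmax(min_reads, round(vaf * total))
  data.frame(
    sample_id = sample_id, gene = gene,
    chrom = gene_map$chrom[gi],
    pos = gene_map$pos_base[gi] + sample.int(5000, n, replace = TRUE),
    ref = contexts$ref, alt = contexts$alt,
    mutant_reads = mutant, total_reads = total,
    vaf = mutant / total,
    is_cosmic_hotspot = hotspot, in_repeat_region = FALSE,
    is_known_driver = driver, context3 = contexts$context3,
    stringsAsFactors = FALSE
  )
}

empty_variants <- function() {
  data.frame(sample_id = character(), gene = character(),
             chrom = character(), pos = integer(), ref = character(),
             alt = character(), mutant_reads = integer(),
             total_reads = integer(), vaf = numeric(),
             is_cosmic_hotspot = logical(), in_repeat_region = logical(),
             is_known_driver = logical(), context3 = character(),
             stringsAsFactors = FALSE)
}

#' Simulate a synthetic gastric cancer cohort
#'
#' Generates, deterministically for a given seed, the four input tables
#' the pipeline consumes -- clinical records, somatic variant candidates,
#' the per-gene log2 depth-ratio matrix and the indel-site instability
#' calls -- plus a panel-of-normals blacklist for the planted filter
#' fodder and a `truth` record storing every planted parameter for
#' recovery tests.
#'
#' Each patient carries a latent subtype: EBV patients get the EBV flag,
#' MSI patients draw unstable indel sites at the high rate, CIN patients
#' receive enough random gene-level gains/losses that their expected CIS
#' exceeds the CIN cut. Binary alteration features are drawn per age
#' group with the probability implied by the configured baseline
#' frequency and odds ratio. Planted copy-number abnormalities for CIN
#' patients avoid the genes and arms carrying planted features, so the
#' planted odds ratios stay identifiable.
#'
#' @param config A [simulation_config()].
#' @return List with `clinical`, `variants`, `log2` (a
#'   [gene_log2_matrix()]), `sites` (logical matrix), `normal_panel`
#'   (a [normal_panel_index()]), and `truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_patients
  gene_map <- build_gene_panel(config)
  fs <- config$feature_spec
  seeds <- derive_seeds(config$seed, 8)

  if (n == 0) {
    l2 <- matrix(numeric(0), nrow = 0, ncol = nrow(gene_map),
                 dimnames = list(character(0), gene_map$gene))
    sites <- matrix(logical(0), nrow = 0, ncol = config$n_sites,
                    dimnames = list(character(0),
                                    sprintf("site%02d", seq_len(config$n_sites))))
    return(list(
      clinical = data.frame(sample_id = character(), age = integer(),
                            sex = character(), ebv_positive = logical(),
                            purity = numeric(), stringsAsFactors = FALSE),
      variants = empty_variants(),
      log2 = gene_log2_matrix(l2, gene_map[, c("gene", "chrom", "arm")]),
      sites = sites,
      normal_panel = normal_panel_index(),
      truth = build_truth(config, fs, NULL)
    ))
  }

  ids <- sprintf("P%05d", seq_len(n))

  # -- clinical: age, sex, latent subtype ---------------------------------
  clin <- with_seed(seeds[1], {
    young <- stats::runif(n) < config$young_frac
    lo <- config$age_range[1]; hi <- config$age_range[2]
    age <- integer(n)
    cut <- config$age_cutoff
    if (any(young))
      age[young] <- discrete_truncnorm(sum(young), lo, cut - 1L,
                                       config$age_mean, config$age_sd)
    if (any(!young))
      age[!young] <- discrete_truncnorm(sum(!young), cut, hi,
                                        config$age_mean, config$age_sd)
    p_male <- ifelse(young,
                     config$male_odds_young / (1 + config$male_odds_young),
                     config$male_odds_old / (1 + config$male_odds_old))
    sex <- ifelse(stats::runif(n) < p_male, "male", "female")
    probs_old <- config$subtype_probs[c("EBV", "MSI", "CIN", "GS")]
    probs_young <- probs_old
    probs_young["GS"] <- probs_young["GS"] +
      probs_young["CIN"] * (1 - config$cin_young_factor)
    probs_young["CIN"] <- probs_young["CIN"] * config$cin_young_factor
    subtype <- character(n)
    if (any(young))
      subtype[young] <- sample(names(probs_young), sum(young),
                               replace = TRUE, prob = probs_young)
    if (any(!young))
      subtype[!young] <- sample(names(probs_old), sum(!young),
                                replace = TRUE, prob = probs_old)
    purity <- 0.2 + 0.8 * stats::rbeta(n, 2, 2)
    missing_age <- sample.int(n, config$n_missing_age)
    data.frame(sample_id = ids, age = age, young = young, sex = sex,
               subtype = subtype, purity = purity,
               age_missing = seq_len(n) %in% missing_age,
               stringsAsFactors = FALSE)
  })

  # -- planted alteration features ----------------------------------------
  carriers <- with_seed(seeds[2], {
    if (nrow(fs) == 0) {
      matrix(FALSE, n, 0)
    } else {
      p_young <- implied_young_prob(fs$freq_old, fs$or_young)
      sapply(seq_len(nrow(fs)), function(j) {
        p <- ifelse(clin$young, p_young[j], fs$freq_old[j])
        stats::runif(n) < p
      })
    }
  })
  if (nrow(fs) > 0) colnames(carriers) <- fs$feature

  # -- log2 depth-ratio matrix --------------------------------------------
  G <- nrow(gene_map)
  feature_arms <- unique(c(
    paste0(FEATURE_GENE_MAP$chrom, FEATURE_GENE_MAP$arm),
    fs$target[fs$class %in% c("arm_gain", "arm_loss")]
  ))
  gene_arm <- paste0(gene_map$chrom, gene_map$arm)
  cin_eligible <- !(gene_map$gene %in% FEATURE_GENE_MAP$gene) &
    !(gene_arm %in% feature_arms)
  l2 <- with_seed(seeds[3], {
    m <- matrix(stats::rnorm(n * G, 0, config$cnv_noise_sd), n, G,
                dimnames = list(ids, gene_map$gene))
    # background instability rising with age (drives the CIS trend)
    bg_frac <- pmin(0.2, pmax(0, 0.01 +
                                config$bg_instability_slope * (clin$age - 20)))
    bg_mask <- matrix(stats::runif(n * G) < bg_frac, n, G)
    amp <- matrix(stats::runif(n * G, 0.25, 0.45) *
                    sign(stats::runif(n * G) - 0.5), n, G)
    m[bg_mask] <- amp[bg_mask]
    # CIN subtype: dense random gains/losses on eligible genes
    is_cin <- clin$subtype == "CIN"
    if (any(is_cin) && any(cin_eligible)) {
      cin_mask <- matrix(FALSE, n, G)
      cin_mask[is_cin, cin_eligible] <-
        stats::runif(sum(is_cin) * sum(cin_eligible)) < config$cin_abnormal_frac
      cin_val <- matrix(ifelse(stats::runif(n * G) < 0.5,
                               config$gain_log2, config$loss_log2), n, G)
      m[cin_mask] <- cin_val[cin_mask]
    }
    # planted arm shifts
    for (j in which(fs$class %in% c("arm_gain", "arm_loss"))) {
      gj <- gene_arm == fs$target[j]
      shift <- if (fs$class[j] == "arm_gain") config$arm_shift
               else -config$arm_shift
      m[carriers[, j], gj] <- m[carriers[, j], gj] + shift
    }
    # planted gene-level CNVs (overwrite, so carriers are always called)
    for (j in which(fs$class %in% c("cnv_gain", "cnv_loss"))) {
      gj <- which(gene_map$gene == fs$target[j])
      val <- if (fs$class[j] == "cnv_gain") config$gain_log2
             else config$loss_log2
      ci <- which(carriers[, j])
      m[ci, gj] <- val + stats::rnorm(length(ci), 0, config$cnv_noise_sd)
    }
    m
  })

  # -- indel-site instability calls ---------------------------------------
  sites <- with_seed(seeds[4], {
    rate <- ifelse(clin$subtype == "MSI",
                   config$msi_site_rate_pos, config$msi_site_rate_neg)
    matrix(stats::runif(n * config$n_sites) < rate, n, config$n_sites,
           dimnames = list(ids, sprintf("site%02d",
                                        seq_len(config$n_sites))))
  })

  # -- variant candidates -------------------------------------------------
  variants <- with_seed(seeds[5], {
    rows <- list()
    mut_idx <- which(fs$class == "mutation")
    for (j in mut_idx) {
      ci <- which(carriers[, j])
      if (length(ci) == 0) next
      ctx <- draw_snv_contexts(length(ci), config$signature_probs)
      rows[[length(rows) + 1]] <-
        make_variant_rows(ids[ci], fs$target[j], gene_map, ctx,
                          hotspot = TRUE, driver = TRUE)
    }
    lambda <- config$tmb_base *
      exp(config$tmb_age_slope * (clin$age - 60) / 10) *
      ifelse(clin$subtype == "MSI", config$msi_tmb_mult, 1)
    np <- stats::rpois(n, lambda)
    if (sum(np) > 0) {
      sid <- rep(ids, np)
      bg_genes <- gene_map$gene[grepl("^BG", gene_map$gene)]
      gene <- sample(bg_genes, sum(np), replace = TRUE)
      ctx <- draw_snv_contexts(sum(np), config$signature_probs)
      driver <- stats::runif(sum(np)) < config$driver_fraction
      rows[[length(rows) + 1]] <-
        make_variant_rows(sid, gene, gene_map, ctx,
                          hotspot = FALSE, driver = driver)
    }
    if (length(rows) == 0) empty_variants() else do.call(rbind, rows)
  })

  # -- filter fodder + panel-of-normals blacklist -------------------------
  panel <- normal_panel_index()
  if (config$fodder_n > 0) {
    fodder <- with_seed(seeds[7], {
      nf <- config$fodder_n
      mode <- rep(c("blacklist", "repeat", "evidence"), length.out = nf)
      sid <- sample(ids, nf, replace = TRUE)
      bg_genes <- gene_map$gene[grepl("^BG", gene_map$gene)]
      gene <- sample(bg_genes, nf, replace = TRUE)
      ctx <- draw_snv_contexts(nf, config$signature_probs)
      v <- make_variant_rows(sid, gene, gene_map, ctx,
                             hotspot = FALSE, driver = FALSE)
      # deterministic positions so blacklist keys can be indexed
      v$pos <- gene_map$pos_base[match(gene, gene_map$gene)] +
        900000L + seq_len(nf)
      v$in_repeat_region <- mode == "repeat"
      weak <- mode == "evidence"
      v$mutant_reads[weak] <- 4L
      v$total_reads[weak] <- 400L
      v$vaf[weak] <- 0.01
      v$is_cosmic_hotspot[weak] <- FALSE
      list(variants = v, blacklist = v[mode == "blacklist", , drop = FALSE])
    })
    variants <- rbind(variants, fodder$variants)
    if (nrow(fodder$blacklist) > 0)
      panel <- normal_panel_index(data.frame(
        chrom = fodder$blacklist$chrom, pos = fodder$blacklist$pos,
        ref = fodder$blacklist$ref, alt = fodder$blacklist$alt,
        fraction = 0.2, stringsAsFactors = FALSE), n_normals = 500L)
  }

  clinical <- data.frame(
    sample_id = clin$sample_id,
    age = ifelse(clin$age_missing, NA_integer_, clin$age),
    sex = clin$sex,
    ebv_positive = clin$subtype == "EBV",
    purity = clin$purity,
    stringsAsFactors = FALSE
  )

  list(
    clinical = clinical,
    variants = variants,
    log2 = gene_log2_matrix(l2, gene_map[, c("gene", "chrom", "arm")]),
    sites = sites,
    normal_panel = panel,
    truth = build_truth(config, fs, clin, carriers)
  )
}

build_truth <- function(config, fs, clin, carriers = NULL) {
  feat <- if (nrow(fs) > 0)
    cbind(fs, p_young = implied_young_prob(fs$freq_old, fs$or_young))
  else fs
  truth <- list(
    seed = config$seed,
    n_patients = config$n_patients,
    young_frac = config$young_frac,
    age_cutoff = config$age_cutoff,
    age_mean = config$age_mean, age_sd = config$age_sd,
    male_odds_young = config$male_odds_young,
    male_odds_old = config$male_odds_old,
    subtype_probs = as.list(config$subtype_probs),
    cin_young_factor = config$cin_young_factor,
    msi_site_rate_pos = config$msi_site_rate_pos,
    msi_site_rate_neg = config$msi_site_rate_neg,
    tmb_base = config$tmb_base, tmb_age_slope = config$tmb_age_slope,
    msi_tmb_mult = config$msi_tmb_mult,
    cnv_noise_sd = config$cnv_noise_sd,
    cin_abnormal_frac = config$cin_abnormal_frac,
    bg_instability_slope = config$bg_instability_slope,
    features = feat
  )
  if (!is.null(clin))
    truth$latent <- data.frame(
      sample_id = clin$sample_id, age = clin$age, young = clin$young,
      subtype = clin$subtype, stringsAsFactors = FALSE)
  if (!is.null(carriers)) truth$carriers <- carriers
  truth
}

#' Simulate an MSI assay validation set
#'
#' Emits truth labels and assay calls for `n_pos` MSI-positive and
#' `n_neg` MSI-negative samples such that exactly `round(sens * n_pos)`
#' positives and `round(spec * n_neg)` negatives are called correctly
#' (deterministic counts; which samples are miscalled is randomized by
#' the seed).
#'
#' @param n_pos,n_neg Numbers of truly positive / negative samples.
#' @param sens,spec Target sensitivity and specificity.
#' @param seed Integer seed.
#' @return `data.frame` with `sample_id`, `truth`, `call` (logicals).
#' @export
simulate_msi_validation <- function(n_pos, n_neg, sens, spec, seed = 1) {
  stopifnot(n_pos >= 0, n_neg >= 0, sens >= 0, sens <= 1,
            spec >= 0, spec <= 1)
  n <- n_pos + n_neg
  truth <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
  call <- logical(n)
  with_seed(seed, {
    tp <- round(sens * n_pos)
    tn <- round(spec * n_neg)
    if (n_pos > 0) call[sample.int(n_pos, tp)] <- TRUE
    if (n_neg > 0) call[n_pos + sample.int(n_neg, n_neg - tn)] <- TRUE
  })
  data.frame(sample_id = sprintf("V%03d", seq_len(n)),
             truth = truth, call = call, stringsAsFactors = FALSE)
}

#' Exhaustive search over integer confusion matrices
#'
#' Enumerates all ways to split `n_total` validation samples into
#' positives and negatives with integer true-positive and true-negative
#' counts whose sensitivity and specificity round (to `digits` decimals,
#' in percent) to the stated values, and reports each candidate's
#' accuracy.
#'
#' @param n_total Total validation samples.
#' @param sens_pct,spec_pct Printed sensitivity/specificity in percent.
#' @param digits Decimal places of the printed percentages.
#' @return `data.frame` with `n_pos`, `n_neg`, `tp`, `tn`,
#'   `accuracy_pct`, one row per consistent matrix.
#' @export
msi_confusion_search <- function(n_total = 90, sens_pct = 96.8,
                                 spec_pct = 94.9, digits = 1) {
  out <- list()
  for (n_pos in seq_len(n_total - 1)) {
    n_neg <- n_total - n_pos
    tp <- 0:n_pos
    tp <- tp[round(100 * tp / n_pos, digits) == sens_pct]
    tn <- 0:n_neg
    tn <- tn[round(100 * tn / n_neg, digits) == spec_pct]
    if (length(tp) == 0 || length(tn) == 0) next
    grid <- expand.grid(tp = tp, tn = tn)
    out[[length(out) + 1]] <- data.frame(
      n_pos = n_pos, n_neg = n_neg, tp = grid$tp, tn = grid$tn,
      accuracy_pct = round(100 * (grid$tp + grid$tn) / n_total, digits))
  }
  if (length(out) == 0)
    return(data.frame(n_pos = integer(), n_neg = integer(),
                      tp = integer(), tn = integer(),
                      accuracy_pct = numeric()))
  do.call(rbind, out)
}
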