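# Per-patient genomic-instability scores: MSI fraction over the indel-site
# panel, tumor mutational burden, gene- and arm-level copy-number calls,
# and the chromosomal instability score (CIS).

#' Score thresholds
#'
#' Collects every cut used by the scoring and subtyping stages, with the
#' panel's validated defaults.
#'
#' @param msi_cut MSI classification cut on the unstable-site fraction
#'   (default 0.40).
#' @param msi_comparator `">="` (default, the subtyping convention) or
#'   `">"` for a strict cut at `msi_cut`.
#' @param cnv_log2_cut Gene copy-number call threshold on |log2 depth
#'   ratio| (default 0.6, inclusive).
#' @param abnormal_log2_cut CIS "abnormal copy number" threshold on |log2
#'   depth ratio| (default 0.2, strict).
#' @param cis_class_cut CIN classification cut on the CIS (default 0.25).
#' @param arm_log2_cut Arm-level call threshold on the arm median |log2|
#'   (default 0.2, inclusive).
#' @param cis_weighting `"chromosome"` (default): CIS is the unweighted
#'   mean of per-autosome abnormal fractions; `"gene"`: pooled abnormal
#'   fraction over all autosomal genes.
#' @return An object of class `score_thresholds`.
#' @export
score_thresholds <- function(msi_cut = 0.40,
                             msi_comparator = c(">=", ">"),
                             cnv_log2_cut = 0.6,
                             abnormal_log2_cut = 0.2,
                             cis_class_cut = 0.25,
                             arm_log2_cut = 0.2,
                             cis_weighting = c("chromosome", "gene")) {
  msi_comparator <- match.arg(msi_comparator)
  cis_weighting <- match.arg(cis_weighting)
  stopifnot(msi_cut > 0, cnv_log2_cut > 0, abnormal_log2_cut > 0,
            cis_class_cut > 0, arm_log2_cut > 0)
  if (abnormal_log2_cut >= cnv_log2_cut)
    stop_config("abnormal_log2_cut must be below cnv_log2_cut")
  structure(list(msi_cut = msi_cut, msi_comparator = msi_comparator,
                 cnv_log2_cut = cnv_log2_cut,
                 abnormal_log2_cut = abnormal_log2_cut,
                 cis_class_cut = cis_class_cut, arm_log2_cut = arm_log2_cut,
                 cis_weighting = cis_weighting),
            class = "score_thresholds")
}

#' MSI score from indel-site instability calls
#'
#' The MSI score of a sample is the fraction of panel indel sites called
#' unstable relative to control; a sample is MSI-positive when the score
#' reaches the classification cut (default: score >= 0.40).
#'
#' @param calls Logical matrix of site calls (samples x sites, as from
#'   [read_site_calls()]), or a single logical vector for one sample.
#' @param thresholds A [score_thresholds()] object.
#' @return `data.frame` with `sample_id`, `msi_score`, `msi_positive`.
#' @export
msi_score <- function(calls, thresholds = score_thresholds()) {
  if (is.vector(calls)) calls <- matrix(calls, nrow = 1,
                                        dimnames = list("sample", NULL))
  if (ncol(calls) == 0)
    stop_validation("MSI score undefined: site panel is empty")
  score <- rowMeans(calls)
  pos <- if (thresholds$msi_comparator == ">=") score >= thresholds$msi_cut
         else score > thresholds$msi_cut
  data.frame(sample_id = rownames(calls), msi_score = unname(score),
             msi_positive = unname(pos), stringsAsFactors = FALSE)
}

#' Tumor mutational burden
#'
#' TMB of a sample is the total number of somatic mutations surviving the
#' filter cascade, excluding known driver mutations.
#'
#' @param variants Filter-cascade survivors (`data.frame` with `sample_id`
#'   and `is_known_driver`).
#' @param sample_ids Optional vector of sample ids; samples without
#'   variants get TMB 0 and the result follows this order.
#' @return `data.frame` with `sample_id`, `tmb`.
#' @export
tmb <- function(variants, sample_ids = NULL) {
  if (is.null(sample_ids))
    sample_ids <- unique(as.character(variants$sample_id))
  n <- table(factor(variants$sample_id[!variants$is_known_driver],
                    levels = sample_ids))
  data.frame(sample_id = sample_ids, tmb = as.integer(n),
             stringsAsFactors = FALSE)
}

#' Gene-level copy-number call from a log2 depth ratio
#'
#' Gain iff log2 >= +cut, loss iff log2 <= -cut (default cut 0.6,
#' boundary inclusive), neutral otherwise.
#'
#' @param log2ratio Numeric vector of log2 depth ratios.
#' @param thresholds A [score_thresholds()] object.
#' @return Character vector in `{"gain", "loss", "neutral"}`.
#' @export
call_gene_cnv <- function(log2ratio, thresholds = score_thresholds()) {
  if (any(!is.finite(log2ratio)))
    stop_validation("non-finite log2 depth ratio")
  cut <- thresholds$cnv_log2_cut
  ifelse(log2ratio >= cut, "gain",
         ifelse(log2ratio <= -cut, "loss", "neutral"))
}

#' Gene copy-number call table for a cohort
#'
#' @param l2m A [gene_log2_matrix()].
#' @param thresholds A [score_thresholds()] object.
#' @return Long `data.frame` (`sample_id`, `gene`, `call`) listing
#'   non-neutral calls only; samples with no gains/losses are absent.
#' @export
cnv_call_table <- function(l2m, thresholds = score_thresholds()) {
  m <- l2m$log2ratio
  calls <- call_gene_cnv(as.vector(m), thresholds)
  idx <- which(calls != "neutral")
  r <- ((idx - 1) %% nrow(m)) + 1
  cc <- ((idx - 1) %/% nrow(m)) + 1
  data.frame(sample_id = rownames(m)[r], gene = colnames(m)[cc],
             call = calls[idx], stringsAsFactors = FALSE)
}

#' Chromosomal instability score (CIS)
#'
#' A gene has abnormal copy number when its |log2 depth ratio| is strictly
#' above the abnormal cut (default 0.2). Under the default chromosome
#' weighting the CIS of a sample is the mean, over the autosomes
#' (1..22) represented on the panel, of each autosome's abnormal-gene
#' fraction; under gene weighting it is the pooled abnormal fraction over
#' all autosomal genes. Sex chromosomes never contribute.
#'
#' @param l2m A [gene_log2_matrix()].
#' @param thresholds A [score_thresholds()] object.
#' @return `data.frame` with `sample_id`, `cis` (in `[0, 1]`).
#' @export
cis <- function(l2m, thresholds = score_thresholds()) {
  auto <- l2m$gene_map$chrom %in% as.character(1:22)
  if (!any(auto))
    stop_validation("CIS undefined: no autosomal genes on the panel")
  m <- l2m$log2ratio[, auto, drop = FALSE]
  chrom <- factor(l2m$gene_map$chrom[auto])
  abn <- abs(m) > thresholds$abnormal_log2_cut
  if (thresholds$cis_weighting == "gene") {
    val <- rowMeans(abn)
  } else {
    # per-chromosome abnormal fraction, then unweighted mean over autosomes
    ind <- do.call(cbind, lapply(levels(chrom),
                                 function(cc) as.numeric(chrom == cc)))
    counts <- abn %*% ind
    per_chrom <- sweep(counts, 2, colSums(ind), "/")
    val <- rowMeans(per_chrom)
  }
  data.frame(sample_id = rownames(m), cis = unname(val),
             stringsAsFactors = FALSE)
}

#' Arm-level copy-number calls
#'
#' Summarizes each chromosome arm by the median gene log2 depth ratio on
#' the arm; arm gain iff the median is at or above `+arm_log2_cut`, loss
#' iff at or below the negative cut (default 0.2). Arms with no panel
#' genes yield no call.
#'
#' @param l2m A [gene_log2_matrix()].
#' @param thresholds A [score_thresholds()] object.
#' @return Long `data.frame` (`sample_id`, `arm`, `call`) over every
#'   represented arm, including neutral calls.
#' @export
call_arm_cnv <- function(l2m, thresholds = score_thresholds()) {
  arm <- paste0(l2m$gene_map$chrom, l2m$gene_map$arm)
  arms <- unique(arm)
  cut <- thresholds$arm_log2_cut
  out <- lapply(arms, function(a) {
    med <- apply(l2m$log2ratio[, arm == a, drop = FALSE], 1, stats::median)
    data.frame(sample_id = rownames(l2m$log2ratio), arm = a,
               call = ifelse(med >= cut, "gain",
                             ifelse(med <= -cut, "loss", "neutral")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-patient score table
#'
#' Computes MSI score, TMB and CIS for every sample and merges them into
#' one table.
#'
#' @param kept_variants Filter-cascade survivors.
#' @param l2m A [gene_log2_matrix()].
#' @param site_calls Logical matrix of indel-site calls.
#' @param thresholds A [score_thresholds()] object.
#' @param sample_ids Sample universe; defaults to the log2 matrix rows.
#' @return `data.frame` with `sample_id`, `msi_score`, `msi_positive`,
#'   `tmb`, `cis`.
#' @export
compute_scores <- function(kept_variants, l2m, site_calls,
                           thresholds = score_thresholds(),
                           sample_ids = rownames(l2m$log2ratio)) {
  msi <- msi_score(site_calls[sample_ids, , drop = FALSE], thresholds)
  burden <- tmb(kept_variants, sample_ids)
  instab <- cis(l2m, thresholds)
  out <- merge(msi, burden, by = "sample_id", sort = FALSE)
  out <- merge(out, instab, by = "sample_id", sort = FALSE)
  out[match(sample_ids, out$sample_id), , drop = FALSE]
}
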