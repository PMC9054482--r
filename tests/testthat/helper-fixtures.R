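# Shared fixtures and independent oracles used across the suite.

# Variant-row builder with passing-by-default evidence.
make_variants <- function(n = 1, sample_id = "S1", gene = "TP53",
                          chrom = "17", pos = seq_len(n) + 1000L,
                          ref = "C", alt = "T",
                          mutant_reads = 30L, total_reads = 300L,
                          vaf = NULL, hotspot = FALSE,
                          repeat_region = FALSE, driver = FALSE,
                          context3 = NA_character_) {
  df <- data.frame(sample_id = sample_id, gene = gene, chrom = chrom,
                   pos = pos, ref = ref, alt = alt,
                   mutant_reads = as.integer(mutant_reads),
                   total_reads = as.integer(total_reads),
                   vaf = 0, is_cosmic_hotspot = hotspot,
                   in_repeat_region = repeat_region,
                   is_known_driver = driver, context3 = context3,
                   stringsAsFactors = FALSE)
  df$vaf <- if (is.null(vaf)) df$mutant_reads / df$total_reads else vaf
  df[seq_len(n), , drop = FALSE]
}

make_l2m <- function(mat, chrom, arm, genes = NULL, samples = NULL) {
  mat <- rbind(mat)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(ncol(mat)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(nrow(mat)))
  dimnames(mat) <- list(samples, genes)
  gene_log2_matrix(mat, data.frame(gene = genes, chrom = as.character(chrom),
                                   arm = arm, stringsAsFactors = FALSE))
}

# combn() treats a length-1 numeric x as seq_len(x); force set semantics.
combn_sets <- function(x, m) {
  if (length(x) == 1) return(if (m == 1) list(x) else list())
  utils::combn(x, m, simplify = FALSE)
}

# Exact permutation distribution of the Cuzick statistic T = sum(l_g * r)
# for N distinct values (ranks 1..N), group sizes ng, scores 1..k.
# Distinct rank-to-group assignments are equiprobable.
trend_perm_dist <- function(ng, scores = seq_along(ng)) {
  k <- length(ng)
  N <- sum(ng)
  res <- numeric(0)
  rec <- function(avail, gi, acc) {
    if (gi > k) {
      res[length(res) + 1] <<- acc
      return()
    }
    for (s in combn_sets(avail, ng[gi]))
      rec(setdiff(avail, s), gi + 1, acc + scores[gi] * sum(s))
  }
  rec(seq_len(N), 1, 0)
  res
}

# Same, but over supplied midranks r (ties allowed): T = sum over groups
# of score_g * sum of the midranks assigned to group g.
trend_perm_ranks <- function(r, ng, scores = seq_along(ng)) {
  k <- length(ng)
  res <- numeric(0)
  rec <- function(avail, gi, acc) {
    if (gi > k) {
      res[length(res) + 1] <<- acc
      return()
    }
    for (s in combn_sets(avail, ng[gi]))
      rec(setdiff(avail, s), gi + 1, acc + scores[gi] * sum(r[s]))
  }
  rec(seq_along(r), 1, 0)
  res
}

# Hand Benjamini-Hochberg step-up, independent of stats::p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-sided Fisher p for a 2x2 table by direct hypergeometric enumeration.
fisher_oracle_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); kk <- sum(tab[, 1])
  support <- max(0, kk - n):min(kk, m)
  probs <- stats::dhyper(support, m, n, kk)
  p_obs <- stats::dhyper(tab[1, 1], m, n, kk)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

match_signatures_for_test <- function(A, B) eogc:::match_signatures(A, B)

# All compositions of N into k positive parts.
compositions <- function(N, k) {
  if (k == 1) return(list(N))
  out <- list()
  for (i in 1:(N - k + 1))
    for (rest in compositions(N - i, k - 1))
      out[[length(out) + 1]] <- c(i, rest)
  out
}

# Apply the three filter predicates in an arbitrary stage order; returns
# the kept set (for the order-invariance property).
cascade_in_order <- function(variants, index, order) {
  v <- variants
  for (stage in order) {
    v <- switch(stage,
                blacklist = filter_blacklist(v, index)$kept,
                repeats = filter_repeats(v)$kept,
                evidence = filter_evidence(v)$kept)
  }
  v
}
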