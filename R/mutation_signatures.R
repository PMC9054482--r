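# 96-motif mutational-signature catalog and NMF decomposition.
#
# Substitutions are normalized to the pyrimidine-centred convention: the six
# classes C>A, C>G, C>T, T>A, T>C, T>G crossed with the 16 combinations of
# 5' and 3' flanking bases give the 96 canonical motifs, written e.g.
# "A[C>T]G". A purine reference base is mapped to the reverse-complement
# strand before tallying.

SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' The 96 canonical trinucleotide motifs
#'
#' @return Character vector of the 96 motif labels, ordered by substitution
#'   class then 5' then 3' flank.
#' @export
motif_levels <- function() {
  unlist(lapply(SUBSTITUTION_CLASSES, function(s)
    as.vector(t(outer(BASES, BASES, function(f, t3)
      paste0(f, "[", s, "]", t3))))))
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Reverse complement of each element.
#' @export
revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, NULL), function(s)
           paste(rev(s), collapse = ""), character(1)))
}

# Classify each record as an SNV usable for motif tallying; returns the
# motif label, or NA with a reason.
motif_of <- function(ref, alt, context3) {
  n <- length(ref)
  motif <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  is_snv <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% BASES & alt %in% BASES & ref != alt
  reason[!is_snv] <- "not_snv"
  ok <- is_snv & !is.na(context3) & nchar(context3) == 3 &
    grepl("^[ACGT]{3}$", context3)
  reason[is_snv & !ok] <- "bad_context"
  mid <- substr(context3, 2, 2)
  mism <- ok & mid != ref
  reason[mism] <- "context_ref_mismatch"
  ok <- ok & !mism
  if (any(ok)) {
    r <- ref[ok]; a <- alt[ok]; ctx <- context3[ok]
    flip <- r %in% c("A", "G")
    r[flip] <- chartr("ACGT", "TGCA", r[flip])
    a[flip] <- chartr("ACGT", "TGCA", a[flip])
    ctx[flip] <- revcomp(ctx[flip])
    motif[ok] <- paste0(substr(ctx, 1, 1), "[", r, ">", a, "]",
                        substr(ctx, 3, 3))
  }
  list(motif = motif, reason = reason)
}

#' Tally SNVs into a 96-motif catalog
#'
#' Counts single-nucleotide variants by trinucleotide motif, per group (or
#' per sample). Purine-centred substitutions are mapped to the reverse
#' complement. Non-SNV records are skipped; SNVs whose 3-base context does
#' not match the reference base are rejected; both are reported.
#'
#' @param variants Variant `data.frame` with `ref`, `alt`, `context3`.
#' @param group Grouping vector (one value per variant row); default one
#'   pooled group named `"all"`.
#' @return List with `counts` (groups x 96 integer matrix) and `skipped`
#'   (`data.frame` of reason/count for records not tallied).
#' @export
tally_motifs <- function(variants, group = NULL) {
  if (is.null(group)) group <- rep("all", nrow(variants))
  stopifnot(length(group) == nrow(variants))
  group <- as.character(group)
  lv <- motif_levels()
  m <- motif_of(as.character(variants$ref), as.character(variants$alt),
                as.character(variants$context3))
  glev <- unique(group)
  counts <- matrix(0L, nrow = length(glev), ncol = length(lv),
                   dimnames = list(glev, lv))
  ok <- !is.na(m$motif)
  if (any(ok)) {
    tab <- table(factor(group[ok], glev), factor(m$motif[ok], lv))
    counts[] <- as.integer(tab)
  }
  tab <- table(m$reason[!ok])
  skipped <- data.frame(reason = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
  list(counts = counts, skipped = skipped)
}

#' Non-negative matrix factorization of a motif catalog
#'
#' Factorizes the 96 x m count matrix V into signatures W (96 x k,
#' column-stochastic) and exposures H (k x m) by Frobenius multiplicative
#' updates (Lee-Seung). The reconstruction error is non-increasing over
#' iterations and the factorization is deterministic given `seed`.
#'
#' @param catalog Motif counts: either a groups/samples x 96 matrix (as from
#'   [tally_motifs()]) or a 96 x m matrix.
#' @param k Number of signatures, `1 <= k <= min(96, m)`.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum number of update sweeps.
#' @param tol Relative decrease of the Frobenius error below which the
#'   iteration stops.
#' @return List with `signatures` (96 x k, columns sum to 1), `exposures`
#'   (k x m), `error` (final Frobenius norm), `error_trace`, `iterations`.
#' @export
nmf_signatures <- function(catalog, k, seed = 1, max_iter = 500, tol = 1e-8) {
  V <- as.matrix(catalog)
  lv <- motif_levels()
  if (ncol(V) == 96 && !is.null(colnames(V)) && all(colnames(V) == lv))
    V <- t(V)
  if (nrow(V) != 96)
    stop_validation("catalog must have the 96 motifs on one dimension")
  if (any(V < 0)) stop_validation("catalog has negative entries")
  if (sum(V) == 0) stop_validation("catalog is all zero")
  m <- ncol(V)
  if (k < 1 || k > min(96, m))
    stop_validation("k must be in 1..min(96, %d)", m)

  eps <- .Machine$double.eps
  with_seed(seed, {
    W <- matrix(stats::runif(96 * k, 0.1, 1), 96, k)
    H <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  })
  # scale initial factors to the data magnitude
  H <- H * (sum(V) / sum(W %*% H))
  err <- sqrt(sum((V - W %*% H)^2))
  trace <- err
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    new_err <- sqrt(sum((V - W %*% H)^2))
    trace <- c(trace, new_err)
    if (err - new_err < tol * max(err, 1)) { err <- new_err; break }
    err <- new_err
  }
  s <- colSums(W)
  s[s == 0] <- 1
  W <- sweep(W, 2, s, "/")
  H <- sweep(H, 1, s, "*")
  rownames(W) <- lv
  colnames(W) <- rownames(H) <- paste0("S", seq_len(k))
  colnames(H) <- colnames(V)
  list(signatures = W, exposures = H, error = err,
       error_trace = trace, iterations = length(trace) - 1L)
}

#' Cosine similarity between two non-negative vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return Cosine similarity in `[0, 1]` for non-negative inputs; 0 when
#'   either vector is all zero.
#' @export
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Optimal one-to-one matching of signature columns by total cosine
# similarity; exact enumeration over permutations (k is small).
match_signatures <- function(A, B) {
  k <- ncol(A)
  stopifnot(ncol(B) == k, k <= 8)
  S <- outer(seq_len(k), seq_len(k),
             Vectorize(function(i, j) cosine_sim(A[, i], B[, j])))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- NULL; best_tot <- -Inf
  for (p in perms(seq_len(k))) {
    tot <- sum(S[cbind(seq_len(k), p)])
    if (tot > best_tot) { best_tot <- tot; best <- p }
  }
  data.frame(sig_a = colnames(A), sig_b = colnames(B)[best],
             cosine = S[cbind(seq_len(k), best)],
             stringsAsFactors = FALSE)
}

#' Compare two signature decompositions
#'
#' Matches the signature columns of two decompositions one-to-one
#' (maximizing total cosine similarity over all assignments) and reports
#' the per-pair similarity.
#'
#' @param decomp_a,decomp_b Results of [nmf_signatures()] with equal `k`.
#' @return `data.frame` with one row per matched pair: `sig_a`, `sig_b`,
#'   `cosine`.
#' @export
compare_group_signatures <- function(decomp_a, decomp_b) {
  A <- decomp_a$signatures; B <- decomp_b$signatures
  if (ncol(A) != ncol(B))
    stop_validation("decompositions have different k (%d vs %d)",
                    ncol(A), ncol(B))
  match_signatures(A, B)
}
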