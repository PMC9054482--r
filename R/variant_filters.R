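# Somatic-variant filter cascade: panel-of-normals blacklist, repeat-region
# removal, read/VAF evidence. Thresholds follow the sequencing-panel
# convention: "more than N reads" is strict (>), percent-VAF cuts are
# inclusive (>=).

#' Build a panel-of-normals blacklist index
#'
#' Maps a variant key `(chrom, pos, ref, alt)` to the fraction of
#' normal-panel samples in which that variant was seen with supporting
#' evidence (more than 3 mutant reads and at least 1% VAF in the normal).
#' Variants absent from the index have fraction 0.
#'
#' @param df `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `fraction`; may have zero rows.
#' @param n_normals Number of normal samples behind the index (metadata).
#' @return An object of class `normal_panel_index`.
#' @export
normal_panel_index <- function(df = NULL, n_normals = NA_integer_) {
  if (is.null(df))
    df <- data.frame(chrom = character(), pos = integer(),
                     ref = character(), alt = character(),
                     fraction = numeric(), stringsAsFactors = FALSE)
  require_columns(df, c("chrom", "pos", "ref", "alt", "fraction"),
                  "normal panel index")
  if (nrow(df) > 0 && any(df$fraction < 0 | df$fraction > 1))
    stop_validation("normal panel fractions must lie in [0, 1]")
  key <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  structure(list(fraction = stats::setNames(df$fraction, key),
                 n_normals = n_normals),
            class = "normal_panel_index")
}

#' @rdname normal_panel_index
#' @param path Path to a tab-separated index file
#'   (`chrom pos ref alt fraction`).
#' @export
read_normal_panel <- function(path) normal_panel_index(read_tsv_raw(path))

panel_fraction <- function(variants, index) {
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
               sep = ":")
  f <- unname(index$fraction[key])
  f[is.na(f)] <- 0
  f
}

#' Filter recurrent sequencing artifacts against a panel of normals
#'
#' Drops a variant iff its panel-of-normals fraction is strictly greater
#' than `max_fraction` (default 10%): recurrent errors on the platform are
#' removed as artifacts.
#'
#' @param variants Variant `data.frame`.
#' @param index A [normal_panel_index()].
#' @param max_fraction Drop threshold on the panel fraction (strict `>`).
#' @return List with `kept` and `dropped` (the dropped rows carry a
#'   `panel_fraction` audit column).
#' @export
filter_blacklist <- function(variants, index, max_fraction = 0.10) {
  f <- panel_fraction(variants, index)
  drop <- f > max_fraction
  dropped <- variants[drop, , drop = FALSE]
  dropped$panel_fraction <- f[drop]
  list(kept = variants[!drop, , drop = FALSE], dropped = dropped)
}

#' Filter variants in repeat-masked regions
#'
#' @param variants Variant `data.frame` with the `in_repeat_region` flag.
#' @return List with `kept` and `dropped`.
#' @export
filter_repeats <- function(variants) {
  drop <- variants$in_repeat_region
  list(kept = variants[!drop, , drop = FALSE],
       dropped = variants[drop, , drop = FALSE])
}

#' Filter variants on read and VAF evidence
#'
#' A variant is kept iff it is a COSMIC hotspot with more than
#' `hotspot_min_reads` mutant reads and VAF at least `hotspot_min_vaf`,
#' or (hotspot or not) it has more than `min_reads` mutant reads and VAF
#' at least `min_vaf`.
#'
#' @param variants Variant `data.frame`.
#' @param hotspot_min_reads,hotspot_min_vaf Evidence floor for COSMIC
#'   hotspot variants (defaults: reads > 3, VAF >= 0.01).
#' @param min_reads,min_vaf Evidence floor for all other variants
#'   (defaults: reads > 5, VAF >= 0.02).
#' @return List with `kept` and `dropped`.
#' @export
filter_evidence <- function(variants, hotspot_min_reads = 3,
                            hotspot_min_vaf = 0.01,
                            min_reads = 5, min_vaf = 0.02) {
  keep <- (variants$is_cosmic_hotspot &
             variants$mutant_reads > hotspot_min_reads &
             variants$vaf >= hotspot_min_vaf) |
    (variants$mutant_reads > min_reads & variants$vaf >= min_vaf)
  list(kept = variants[keep, , drop = FALSE],
       dropped = variants[!keep, , drop = FALSE])
}

#' Run the full somatic-variant filter cascade
#'
#' Applies, in order: panel-of-normals blacklist, repeat-region removal,
#' read/VAF evidence. The three predicates are independent per variant, so
#' the final kept set does not depend on stage order; the per-stage drop
#' counts refer to this order.
#'
#' @inheritParams filter_blacklist
#' @inheritParams filter_evidence
#' @return List with `kept` (surviving variants), `audit` (dropped rows
#'   with a `stage` column), and `counts` (named vector: `input`,
#'   `blacklist`, `repeats`, `evidence`, `kept`).
#' @export
run_filter_cascade <- function(variants, index = normal_panel_index(),
                               max_fraction = 0.10,
                               hotspot_min_reads = 3, hotspot_min_vaf = 0.01,
                               min_reads = 5, min_vaf = 0.02) {
  s1 <- filter_blacklist(variants, index, max_fraction)
  s2 <- filter_repeats(s1$kept)
  s3 <- filter_evidence(s2$kept, hotspot_min_reads, hotspot_min_vaf,
                        min_reads, min_vaf)
  audit <- rbind(
    if (nrow(s1$dropped) > 0)
      data.frame(stage = "blacklist",
                 s1$dropped[, names(variants), drop = FALSE]),
    if (nrow(s2$dropped) > 0) data.frame(stage = "repeats", s2$dropped),
    if (nrow(s3$dropped) > 0) data.frame(stage = "evidence", s3$dropped)
  )
  if (is.null(audit))
    audit <- data.frame(stage = character(),
                        variants[0, , drop = FALSE])
  counts <- c(input = nrow(variants),
              blacklist = nrow(s1$dropped),
              repeats = nrow(s2$dropped),
              evidence = nrow(s3$dropped),
              kept = nrow(s3$kept))
  list(kept = s3$kept, audit = audit, counts = counts)
}
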