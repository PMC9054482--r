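# Tabular input/output for the four cohort tables and the result tables.
#
# Dialect: tab-separated with header, UTF-8, "." for missing values,
# booleans accepted as {0, 1, true, false} (any case) and written as 0/1.
# Positions are 1-based inclusive; VAF is stored as a fraction in [0, 1].

VARIANT_COLUMNS <- c(
  "sample_id", "gene", "chrom", "pos", "ref", "alt",
  "mutant_reads", "total_reads", "vaf",
  "is_cosmic_hotspot", "in_repeat_region", "is_known_driver"
)

CLINICAL_COLUMNS <- c("sample_id", "age", "sex", "ebv_positive", "purity")

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  utils::read.delim(path, sep = "\t", na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = NA)
}

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.logical(df[[nm]])) df[[nm]] <- as.integer(df[[nm]])
    if (is.factor(df[[nm]])) df[[nm]] <- as.character(df[[nm]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop_format("%s: missing required column(s): %s", what,
                paste(miss, collapse = ", "))
  invisible(df)
}

parse_flag <- function(x, column) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true")] <- TRUE
  out[v %in% c("0", "false")] <- FALSE
  bad <- which(!is.na(v) & is.na(out))
  if (length(bad) > 0)
    stop_format("column '%s': unparseable boolean at row(s) %s", column,
                paste(utils::head(bad, 5), collapse = ", "))
  out
}

#' Read a somatic-variant candidate table
#'
#' Reads a MAF-like TSV of called somatic variant candidates. Required
#' columns: `sample_id`, `gene`, `chrom`, `pos`, `ref`, `alt`,
#' `mutant_reads`, `total_reads`, `vaf`, `is_cosmic_hotspot`,
#' `in_repeat_region`, `is_known_driver`; `context3` (3-base reference
#' context centred on the variant) is optional and used only by the
#' signature module.
#'
#' Rows violating the record invariants (`mutant_reads > total_reads`,
#' `vaf` inconsistent with the read counts by more than 0.01, `ref == alt`)
#' are reported by row number in a validation error.
#'
#' @param path Path to a tab-separated file with header.
#' @return A `data.frame`, one row per variant candidate.
#' @export
read_variants <- function(path) {
  df <- read_tsv_raw(path)
  require_columns(df, VARIANT_COLUMNS, "variants table")
  validate_variants(df)
}

#' Validate a variant candidate table
#'
#' @param df A data.frame with the variant columns (see [read_variants()]).
#' @return The validated data.frame with boolean columns as logicals.
#' @export
validate_variants <- function(df) {
  for (nm in c("is_cosmic_hotspot", "in_repeat_region", "is_known_driver"))
    df[[nm]] <- parse_flag(df[[nm]], nm)
  if (!"context3" %in% names(df)) df$context3 <- NA_character_
  df$pos <- as.integer(df$pos)
  df$mutant_reads <- as.integer(df$mutant_reads)
  df$total_reads <- as.integer(df$total_reads)
  df$vaf <- as.numeric(df$vaf)
  if (nrow(df) == 0) return(df)

  bad <- df$mutant_reads < 0 | df$total_reads <= 0 |
    df$mutant_reads > df$total_reads
  bad <- bad | df$vaf < 0 | df$vaf > 1
  bad <- bad | (!is.na(df$vaf) &
                  abs(df$vaf - df$mutant_reads / df$total_reads) > 0.01)
  bad <- bad | (df$ref == df$alt)
  bad[is.na(bad)] <- TRUE
  if (any(bad))
    stop_validation("invalid variant record(s) at row(s): %s",
                    paste(utils::head(which(bad), 10), collapse = ", "))
  df
}

#' @rdname read_variants
#' @param df Variant table to write.
#' @export
write_variants <- function(df, path) write_tsv(df, path)

#' Read a clinical table
#'
#' Columns: `sample_id`, `age` (years, "." when unknown), `sex`
#' (`male`/`female`), `ebv_positive` (0/1/true/false), `purity` (fraction).
#'
#' @param path Path to a tab-separated file with header.
#' @return A `data.frame`, one row per patient.
#' @export
read_clinical <- function(path) {
  df <- read_tsv_raw(path)
  require_columns(df, CLINICAL_COLUMNS, "clinical table")
  validate_clinical(df)
}

validate_clinical <- function(df) {
  df$age <- as.integer(df$age)
  df$purity <- as.numeric(df$purity)
  df$ebv_positive <- parse_flag(df$ebv_positive, "ebv_positive")
  df$sex <- as.character(df$sex)
  if (nrow(df) == 0) return(df)
  bad_sex <- !is.na(df$sex) & !df$sex %in% c("male", "female")
  if (any(bad_sex))
    stop_validation("sex must be 'male' or 'female'; bad row(s): %s",
                    paste(utils::head(which(bad_sex), 10), collapse = ", "))
  bad <- (!is.na(df$age) & df$age < 0) |
    (!is.na(df$purity) & (df$purity < 0 | df$purity > 1))
  if (any(bad))
    stop_validation("invalid clinical record(s) at row(s): %s",
                    paste(utils::head(which(bad), 10), collapse = ", "))
  df
}

#' @rdname read_clinical
#' @param df Clinical table to write.
#' @export
write_clinical <- function(df, path) write_tsv(df, path)

#' Construct a per-sample, per-gene log2 depth-ratio matrix
#'
#' Container for copy-number log2 depth ratios together with the placement
#' of each panel gene on a chromosome arm. The chromosomal instability
#' score uses autosomes 1..22 only; sex chromosomes are carried but
#' excluded from that computation.
#'
#' @param log2ratio Numeric matrix, samples in rows (rownames = sample ids),
#'   genes in columns (colnames = gene symbols).
#' @param gene_map `data.frame` with columns `gene`, `chrom`
#'   (`1`..`22`, `X`, `Y`) and `arm` (`p`/`q`), covering every matrix column.
#' @return An object of class `gene_log2_matrix`.
#' @export
gene_log2_matrix <- function(log2ratio, gene_map) {
  log2ratio <- as.matrix(log2ratio)
  if (is.null(colnames(log2ratio)) ||
      (nrow(log2ratio) > 0 && is.null(rownames(log2ratio))))
    stop_validation("log2 matrix must carry sample rownames and gene colnames")
  if (is.null(rownames(log2ratio)))
    rownames(log2ratio) <- character(0)
  require_columns(gene_map, c("gene", "chrom", "arm"), "gene map")
  gene_map$chrom <- as.character(gene_map$chrom)
  gene_map$arm <- as.character(gene_map$arm)
  miss <- setdiff(colnames(log2ratio), gene_map$gene)
  if (length(miss) > 0)
    stop_validation("gene map lacks entries for: %s",
                    paste(utils::head(miss, 10), collapse = ", "))
  bad_chrom <- !gene_map$chrom %in% c(as.character(1:22), "X", "Y")
  if (any(bad_chrom))
    stop_validation("gene map: unknown chromosome(s): %s",
                    paste(unique(gene_map$chrom[bad_chrom]), collapse = ", "))
  if (!all(gene_map$arm %in% c("p", "q")))
    stop_validation("gene map: arm must be 'p' or 'q'")
  gene_map <- gene_map[match(colnames(log2ratio), gene_map$gene), , drop = FALSE]
  rownames(gene_map) <- NULL
  structure(list(log2ratio = log2ratio, gene_map = gene_map),
            class = "gene_log2_matrix")
}

#' @export
print.gene_log2_matrix <- function(x, ...) {
  cat(sprintf("gene_log2_matrix: %d samples x %d genes (%d autosomal)\n",
              nrow(x$log2ratio), ncol(x$log2ratio),
              sum(x$gene_map$chrom %in% as.character(1:22))))
  invisible(x)
}

#' Read / write the log2 depth-ratio matrix and its gene map
#'
#' `log2matrix.tsv` holds `sample_id` in the first column and one column per
#' gene; `gene_map.tsv` holds `gene`, `chrom`, `arm`.
#'
#' @param path,map_path Paths to the two tab-separated files.
#' @return A [gene_log2_matrix()] object.
#' @export
read_log2_matrix <- function(path, map_path) {
  df <- read_tsv_raw(path)
  require_columns(df, "sample_id", "log2 matrix")
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$sample_id)
  gene_log2_matrix(m, read_tsv_raw(map_path))
}

#' @rdname read_log2_matrix
#' @param x A `gene_log2_matrix`.
#' @export
write_log2_matrix <- function(x, path, map_path = NULL) {
  df <- data.frame(sample_id = rownames(x$log2ratio),
                   x$log2ratio, check.names = FALSE)
  write_tsv(df, path)
  if (!is.null(map_path)) write_tsv(x$gene_map, map_path)
  invisible(path)
}

#' Read indel-site instability calls
#'
#' One row per sample: `sample_id` plus one 0/1 column per panel indel site
#' (default panel size 52). All samples must carry the same number of sites.
#'
#' @param path Path to a tab-separated file with header.
#' @param panel_size Expected number of site columns; `NULL` to accept any.
#' @return Logical matrix, samples in rows (rownames = sample ids), sites in
#'   columns.
#' @export
read_site_calls <- function(path, panel_size = NULL) {
  df <- read_tsv_raw(path)
  require_columns(df, "sample_id", "site calls table")
  sites <- setdiff(names(df), "sample_id")
  if (!is.null(panel_size) && length(sites) != panel_size)
    stop_validation("site calls: expected %d site columns, found %d",
                    panel_size, length(sites))
  m <- sapply(sites, function(s) parse_flag(df[[s]], s))
  m <- matrix(as.logical(m), nrow = nrow(df), ncol = length(sites),
              dimnames = list(as.character(df$sample_id), sites))
  m
}

#' @rdname read_site_calls
#' @param calls Logical matrix of site calls to write.
#' @export
write_site_calls <- function(calls, path) {
  df <- data.frame(sample_id = rownames(calls),
                   calls + 0L, check.names = FALSE)
  write_tsv(df, path)
}

#' Apply cohort eligibility rules
#'
#' Excludes patients with missing age (clinical bookkeeping) and patients
#' whose tumor purity is not strictly larger than `min_purity` (quality
#' gate; the boundary value is excluded). Every exclusion is recorded with
#' its reason, and eligible plus excluded rows always account for every
#' input row. Patients failing both rules are recorded once, under
#' `missing_age`.
#'
#' @param clinical Clinical `data.frame` (see [read_clinical()]).
#' @param min_purity Purity threshold; kept iff `purity > min_purity`
#'   (default 0.2).
#' @return A list with `eligible` (clinical rows kept) and `excluded`
#'   (`sample_id`, `reason`).
#' @export
assemble_cohort <- function(clinical, min_purity = 0.2) {
  if (anyDuplicated(clinical$sample_id))
    stop_validation("duplicate sample_id(s): %s",
                    paste(utils::head(
                      unique(clinical$sample_id[duplicated(clinical$sample_id)]),
                      5), collapse = ", "))
  reason <- rep(NA_character_, nrow(clinical))
  low_purity <- !is.na(clinical$purity) & clinical$purity <= min_purity
  reason[low_purity] <- "low_purity"
  reason[is.na(clinical$age)] <- "missing_age"
  keep <- is.na(reason)
  list(
    eligible = clinical[keep, , drop = FALSE],
    excluded = data.frame(sample_id = clinical$sample_id[!keep],
                          reason = reason[!keep],
                          stringsAsFactors = FALSE)
  )
}
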