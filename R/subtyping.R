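# Molecular subtyping by the EBV -> MSI -> CIN -> GS cascade.

#' Classify patients into the four gastric cancer molecular subtypes
#'
#' Cascade with first-match precedence: patients with any EBV sequence
#' detected are EBV; of the rest, MSI score at or above the MSI cut gives
#' MSI; then CIS at or above the CIN cut gives CIN; everyone else is
#' genomically stable (GS). Every patient receives exactly one label.
#'
#' @param ebv_positive Logical vector.
#' @param msi_score Numeric vector of unstable-site fractions.
#' @param cis Numeric vector of chromosomal instability scores.
#' @param thresholds A [score_thresholds()] object (uses `msi_cut`,
#'   `msi_comparator`, `cis_class_cut`).
#' @return Factor with levels `c("EBV", "MSI", "CIN", "GS")`.
#' @export
classify_subtype <- function(ebv_positive, msi_score, cis,
                             thresholds = score_thresholds()) {
  stopifnot(length(ebv_positive) == length(msi_score),
            length(msi_score) == length(cis))
  if (anyNA(ebv_positive) || anyNA(msi_score) || anyNA(cis))
    stop_validation("subtype inputs must be non-missing")
  msi_pos <- if (thresholds$msi_comparator == ">=")
    msi_score >= thresholds$msi_cut else msi_score > thresholds$msi_cut
  out <- ifelse(ebv_positive, "EBV",
                ifelse(msi_pos, "MSI",
                       ifelse(cis >= thresholds$cis_class_cut, "CIN", "GS")))
  factor(out, levels = c("EBV", "MSI", "CIN", "GS"))
}

#' Subtype-by-age contingency tables
#'
#' Cross-tabulates subtype against the two-level age group, with a
#' sub-table restricted to the EBV and MSI subtypes (whose proportions are
#' expected to be age-stable).
#'
#' @param subtype Factor of subtypes (as from [classify_subtype()]).
#' @param age_group Factor of two-level age groups (as from
#'   [age_group2()]).
#' @return List with `counts` (4 x 2 table), `proportions` (columns sum to
#'   1 per age group), and `ebv_msi` (2 x 2 sub-table).
#' @export
subtype_by_age_table <- function(subtype, age_group) {
  stopifnot(length(subtype) == length(age_group))
  counts <- table(subtype = subtype, age_group = age_group)
  props <- prop.table(counts, margin = 2)
  props[is.nan(props)] <- 0
  list(counts = counts, proportions = props,
       ebv_msi = counts[rownames(counts) %in% c("EBV", "MSI"), ,
                        drop = FALSE])
}
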