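# Age-group enrichment statistics: per-feature sex-adjusted logistic
# regression (outcome = young at diagnosis), Benjamini-Hochberg FDR,
# Cuzick rank trend test over ordered age bins, and chi-square/Fisher
# categorical contrasts.

#' Build the per-patient binary alteration matrix
#'
#' One column per feature: `<gene>_mut` (at least one kept somatic
#' mutation in the gene), `<gene>_gain` / `<gene>_loss` (gene copy-number
#' calls), and `<arm>_arm_gain` / `<arm>_arm_loss` (arm-level calls).
#' Patients absent from a call table carry `FALSE` for its features
#' (absence means no alteration).
#'
#' @param kept_variants Filter-cascade survivors (`sample_id`, `gene`).
#' @param cnv_calls Gene call table from [cnv_call_table()].
#' @param arm_calls Arm call table from [call_arm_cnv()].
#' @param sample_ids Patient universe defining the row order.
#' @return Logical matrix, samples x features.
#' @export
make_feature_matrix <- function(kept_variants, cnv_calls, arm_calls,
                                sample_ids) {
  sample_ids <- as.character(sample_ids)
  cols <- list()
  ind <- function(sid, label) {
    tab <- table(factor(sid, levels = sample_ids), label)
    m <- tab > 0
    m[, colnames(tab) != "", drop = FALSE]
  }
  if (!is.null(kept_variants) && nrow(kept_variants) > 0)
    cols$mut <- ind(kept_variants$sample_id,
                    paste0(kept_variants$gene, "_mut"))
  if (!is.null(cnv_calls)) {
    cnv <- cnv_calls[cnv_calls$call != "neutral", , drop = FALSE]
    if (nrow(cnv) > 0)
      cols$cnv <- ind(cnv$sample_id, paste0(cnv$gene, "_", cnv$call))
  }
  if (!is.null(arm_calls)) {
    armc <- arm_calls[arm_calls$call != "neutral", , drop = FALSE]
    if (nrow(armc) > 0)
      cols$arm <- ind(armc$sample_id, paste0(armc$arm, "_arm_", armc$call))
  }
  if (length(cols) == 0)
    return(matrix(logical(0), nrow = length(sample_ids), ncol = 0,
                  dimnames = list(sample_ids, NULL)))
  out <- do.call(cbind, cols)
  rownames(out) <- sample_ids
  out
}

feature_class <- function(feature) {
  ifelse(grepl("_mut$", feature), "mutation",
         ifelse(grepl("_arm_(gain|loss)$", feature), "arm", "cnv"))
}

#' Prevalence filter for alteration features
#'
#' A feature enters the association screen only when its prevalence is
#' strictly above `min_prev` in at least one age group.
#'
#' @param features Logical matrix (samples x features).
#' @param age_group Factor of two-level age groups, aligned with the
#'   matrix rows.
#' @param min_prev Prevalence threshold (default 0.05, strict `>`).
#' @return `data.frame` with `feature`, `freq_young`, `freq_old`,
#'   `retained`.
#' @export
prevalence_filter <- function(features, age_group, min_prev = 0.05) {
  stopifnot(nrow(features) == length(age_group))
  young <- age_group == levels(age_group)[1]
  fy <- colMeans(features[young, , drop = FALSE])
  fo <- colMeans(features[!young, , drop = FALSE])
  data.frame(feature = colnames(features),
             freq_young = unname(fy), freq_old = unname(fo),
             retained = unname(fy > min_prev | fo > min_prev),
             stringsAsFactors = FALSE)
}

# Sex-adjusted logistic fit of P(young) on one predictor; Wald inference.
# Returns a one-row data.frame. Separation or non-convergence is flagged
# and the odds ratio reported as missing.
fit_logistic <- function(y, x, sex = NULL) {
  if (length(unique(y)) < 2)
    stop_validation("outcome is constant: both age groups must be non-empty")
  if (length(unique(x)) < 2)
    return(data.frame(odds_ratio = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p_value = 1,
                      converged = FALSE))
  dat <- data.frame(y = as.numeric(y), x = as.numeric(x))
  form <- y ~ x
  if (!is.null(sex)) {
    dat$sex <- as.numeric(sex == "male")   # female = reference
    if (length(unique(dat$sex)) > 1) form <- y ~ x + sex
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)["x"]
  se <- sqrt(diag(stats::vcov(fit)))["x"]
  ok <- fit$converged && !separated && is.finite(beta) && is.finite(se)
  if (!ok)
    return(data.frame(odds_ratio = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p_value = NA_real_,
                      converged = FALSE))
  z <- beta / se
  data.frame(odds_ratio = exp(beta),
             ci_low = exp(beta - stats::qnorm(0.975) * se),
             ci_high = exp(beta + stats::qnorm(0.975) * se),
             p_value = 2 * stats::pnorm(-abs(z)),
             converged = TRUE, row.names = NULL)
}

#' Age-group enrichment of one binary alteration
#'
#' Fits `logit P(young) = b0 + b1 * feature + b2 * sex` by maximum
#' likelihood. The odds ratio `exp(b1)` is the risk of the alteration
#' occurring in young relative to old patients, adjusted for sex; Wald
#' 95% CI and two-sided p-value. On separation or non-convergence the
#' result is flagged and the odds ratio reported as missing; a constant
#' feature yields `p = 1` by convention.
#'
#' @param feature Logical/0-1 vector: alteration present.
#' @param young Logical/0-1 vector: patient in the young group.
#' @param sex Optional vector `"male"`/`"female"` (female is the
#'   reference level).
#' @return One-row `data.frame`: `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `freq_young`, `freq_old`, `converged`.
#' @export
logistic_enrichment <- function(feature, young, sex = NULL) {
  stopifnot(length(feature) == length(young))
  res <- fit_logistic(young, feature, sex)
  res$freq_young <- mean(feature[as.logical(young)])
  res$freq_old <- mean(feature[!as.logical(young)])
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; the result is
#' attached to the original order and invariant to input permutation.
#' `NA` p-values stay `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in `[0, 1]`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_validation("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cuzick rank test for trend across ordered groups
#'
#' Wilcoxon-type trend test. With group scores `l_g = 1..k` (or custom
#' `scores`) and pooled midranks `r_i`, the statistic is
#' `T = sum l_g(i) r_i`; under the null `E[T] = Lbar N(N+1)/2` and
#' `Var[T] = N(N+1)/12 (sum n_g l_g^2 - (sum n_g l_g)^2 / N)` times the
#' tie-correction factor `1 - sum(t^3 - t) / (N^3 - N)`. The z-score is
#' referred to the standard normal; two-sided p-value.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor (or ordered factor) giving each observation's
#'   group; the factor level order defines the trend direction.
#' @param scores Optional numeric group scores (default `1..k`).
#' @return List of class `trend_result`: `statistic`, `expectation`,
#'   `variance`, `z`, `p_value` (two-sided), `group_ns`,
#'   `tie_corrected`, `degenerate`.
#' @export
cuzick_trend <- function(values, groups, scores = NULL) {
  groups <- factor(groups, levels = levels(factor(groups)))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  k <- nlevels(groups)
  if (k < 2) stop_validation("trend test needs at least two groups")
  if (is.null(scores)) scores <- seq_len(k)
  stopifnot(length(scores) == k)
  N <- length(values)
  ng <- as.numeric(table(groups))
  l <- scores[as.integer(groups)]
  r <- rank(values)   # midranks
  Tstat <- sum(l * r)
  Lbar <- sum(ng * scores) / N
  ET <- Lbar * N * (N + 1) / 2
  ties <- table(values)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  VT <- N * (N + 1) / 12 *
    (sum(ng * scores^2) - (sum(ng * scores))^2 / N) * tie_corr
  if (VT <= 0) {
    out <- list(statistic = Tstat, expectation = ET, variance = 0,
                z = NA_real_, p_value = 1, group_ns = ng,
                tie_corrected = any(ties > 1), degenerate = TRUE)
    return(structure(out, class = "trend_result"))
  }
  z <- (Tstat - ET) / sqrt(VT)
  structure(list(statistic = Tstat, expectation = ET, variance = VT,
                 z = z, p_value = 2 * stats::pnorm(-abs(z)),
                 group_ns = ng, tie_corrected = any(ties > 1),
                 degenerate = FALSE),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Cuzick trend: T = %.1f, E[T] = %.1f, z = %.3f, p = %.4g%s\n",
              x$statistic, x$expectation,
              ifelse(is.na(x$z), NaN, x$z), x$p_value,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Chi-square or Fisher contrast of a contingency table
#'
#' Pearson chi-square without continuity correction when every expected
#' cell is at least 5, Fisher's exact test otherwise (exact network
#' algorithm; Monte-Carlo fallback for large sparse tables). The selected
#' method is reported.
#'
#' @param tab Matrix or table of non-negative counts with positive total.
#' @return List: `method` (`"chisq"` or `"fisher"`), `statistic` (chi-square
#'   statistic, `NA` for Fisher), `p_value`, `expected`.
#' @export
categorical_contrast <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || sum(tab) == 0)
    stop_validation("counts must be non-negative with positive total")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ht <- stats::chisq.test(tab, correct = FALSE)
    list(method = "chisq", statistic = unname(ht$statistic),
         p_value = ht$p.value, expected = expected)
  } else {
    ht <- tryCatch(stats::fisher.test(tab),
                   error = function(e)
                     stats::fisher.test(tab, simulate.p.value = TRUE,
                                        B = 1e5))
    list(method = "fisher", statistic = NA_real_,
         p_value = ht$p.value, expected = expected)
  }
}

#' Screen alteration features for age-group enrichment
#'
#' Applies the prevalence filter, fits the sex-adjusted logistic model per
#' retained feature, and adjusts p-values by Benjamini-Hochberg. FDR is
#' computed within each alteration class (mutation / cnv / arm) by
#' default, matching per-class reporting; `fdr_scope = "pooled"` adjusts
#' across all features at once.
#'
#' @param features Logical matrix (samples x features) from
#'   [make_feature_matrix()].
#' @param young Logical vector aligned with rows: patient in young group.
#' @param sex Vector `"male"`/`"female"` aligned with rows.
#' @param min_prev Prevalence threshold (default 0.05).
#' @param fdr_scope `"class"` (default) or `"pooled"`.
#' @param fdr_cut Significance cut on the FDR (default 0.1).
#' @return `data.frame` sorted by FDR: `feature`, `class`, `freq_young`,
#'   `freq_old`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `fdr`,
#'   `converged`, `significant`.
#' @export
test_associations <- function(features, young, sex, min_prev = 0.05,
                              fdr_scope = c("class", "pooled"),
                              fdr_cut = 0.1) {
  fdr_scope <- match.arg(fdr_scope)
  ag <- factor(ifelse(as.logical(young), "young", "old"),
               levels = c("young", "old"))
  prev <- prevalence_filter(features, ag, min_prev)
  keep <- prev$feature[prev$retained]
  if (length(keep) == 0)
    return(data.frame(feature = character(), class = character(),
                      freq_young = numeric(), freq_old = numeric(),
                      odds_ratio = numeric(), ci_low = numeric(),
                      ci_high = numeric(), p_value = numeric(),
                      fdr = numeric(), converged = logical(),
                      significant = logical(), stringsAsFactors = FALSE))
  rows <- lapply(keep, function(f)
    cbind(feature = f, logistic_enrichment(features[, f], young, sex),
          stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$class <- feature_class(out$feature)
  if (fdr_scope == "class") {
    out$fdr <- NA_real_
    for (cl in unique(out$class)) {
      i <- out$class == cl
      out$fdr[i] <- bh_fdr(out$p_value[i])
    }
  } else {
    out$fdr <- bh_fdr(out$p_value)
  }
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_cut
  out <- out[order(out$fdr, out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("feature", "class", "freq_young", "freq_old", "odds_ratio",
          "ci_low", "ci_high", "p_value", "fdr", "converged",
          "significant")]
}

#' Genomic instability versus age
#'
#' Passes TMB and CIS separately, as numeric predictors adjusted for sex,
#' into the logistic model of the two-level age group (BH-FDR over the
#' pair), and tests each score for monotone trend across the four age
#' bins with the Cuzick test.
#'
#' @param scores `data.frame` with `tmb`, `cis`, `age`, `sex` per patient.
#' @param age_cutoff Young/old cutoff in years (default 45).
#' @param age_breaks Interior bin cut points (default `c(45, 55, 65)`).
#' @return List with `associations` (per-score logistic results + FDR)
#'   and `trends` (per-score [cuzick_trend()] summaries).
#' @export
instability_vs_age <- function(scores, age_cutoff = 45,
                               age_breaks = c(45, 55, 65)) {
  young <- age_group2(scores$age, age_cutoff) == "young"
  assoc <- do.call(rbind, lapply(c("tmb", "cis"), function(v)
    cbind(score = v, fit_logistic(young, scores[[v]], scores$sex),
          stringsAsFactors = FALSE)))
  assoc$fdr <- bh_fdr(assoc$p_value)
  bins <- age_group4(scores$age, age_breaks)
  trends <- do.call(rbind, lapply(c("tmb", "cis"), function(v) {
    tr <- cuzick_trend(scores[[v]], bins)
    data.frame(score = v, statistic = tr$statistic, z = tr$z,
               p_value = tr$p_value, degenerate = tr$degenerate,
               stringsAsFactors = FALSE)
  }))
  list(associations = assoc, trends = trends)
}
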