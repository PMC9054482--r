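# End-to-end orchestration: simulate (or read) -> cohort QC -> filter ->
# score -> subtype -> associate -> trend -> signatures, with every
# intermediate table written as TSV and a single JSON run summary.

stage_wrap <- function(stage, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    if (!is.null(out_dir))
      writeLines(sprintf("FAILED at stage '%s': %s", stage,
                         conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = c("eogc_pipeline_error", "error")))
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on either a synthetic cohort (when
#' `config` is a [simulation_config()]) or on input files (when `config`
#' is a named list of paths: `variants`, `clinical`, `log2`, `gene_map`,
#' `sites`, optionally `normal_panel`). All intermediate tables are
#' written to `out_dir` as TSV, plus `truth.json` (simulated runs) and a
#' `summary.json` recording the seed, thresholds, per-stage row counts
#' and headline results. Output is fully determined by inputs, config and
#' seed.
#'
#' @param config A [simulation_config()] or a named list of input paths.
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @param thresholds A [score_thresholds()].
#' @param min_purity Cohort purity gate (kept iff purity > cut).
#' @param min_prev Prevalence threshold of the association screen.
#' @param fdr_cut FDR significance cut (default 0.1).
#' @param age_cutoff,age_breaks Age dichotomy and trend bins (years).
#' @param fdr_scope `"class"` or `"pooled"` FDR adjustment scope.
#' @return Invisibly, a list with every stage result and the `summary`.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         thresholds = score_thresholds(),
                         min_purity = 0.2, min_prev = 0.05, fdr_cut = 0.1,
                         age_cutoff = 45, age_breaks = c(45, 55, 65),
                         fdr_scope = "class") {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  simulated <- inherits(config, "simulation_config")
  inputs <- stage_wrap("input", out_dir, {
    if (simulated) {
      simulate_cohort(config)
    } else {
      req <- c("variants", "clinical", "log2", "gene_map", "sites")
      miss <- setdiff(req, names(config))
      if (length(miss) > 0)
        stop_config("missing input path(s): %s", paste(miss, collapse = ", "))
      list(
        clinical = read_clinical(config$clinical),
        variants = read_variants(config$variants),
        log2 = read_log2_matrix(config$log2, config$gene_map),
        sites = read_site_calls(config$sites),
        normal_panel = if (!is.null(config$normal_panel))
          read_normal_panel(config$normal_panel) else normal_panel_index(),
        truth = NULL
      )
    }
  })

  cohort <- stage_wrap("cohort_qc", out_dir,
                       assemble_cohort(inputs$clinical, min_purity))
  eligible <- cohort$eligible
  ids <- eligible$sample_id

  filt <- stage_wrap("filter", out_dir, {
    v <- inputs$variants[inputs$variants$sample_id %in% ids, , drop = FALSE]
    run_filter_cascade(v, inputs$normal_panel)
  })

  scores <- stage_wrap("score", out_dir, {
    l2 <- inputs$log2
    keep <- rownames(l2$log2ratio) %in% ids
    l2e <- gene_log2_matrix(l2$log2ratio[keep, , drop = FALSE], l2$gene_map)
    compute_scores(filt$kept, l2e,
                   inputs$sites[rownames(inputs$sites) %in% ids, ,
                                drop = FALSE],
                   thresholds, sample_ids = ids)
  })
  cnv_calls <- stage_wrap("cnv_calls", out_dir, {
    l2 <- inputs$log2
    keep <- rownames(l2$log2ratio) %in% ids
    l2e <- gene_log2_matrix(l2$log2ratio[keep, , drop = FALSE], l2$gene_map)
    list(gene = cnv_call_table(l2e, thresholds),
         arm = call_arm_cnv(l2e, thresholds))
  })

  subtypes <- stage_wrap("subtype", out_dir, {
    st <- classify_subtype(eligible$ebv_positive, scores$msi_score,
                           scores$cis, thresholds)
    data.frame(sample_id = ids, subtype = st, stringsAsFactors = FALSE)
  })

  ag2 <- age_group2(eligible$age, age_cutoff)
  tables <- stage_wrap("subtype_tables", out_dir, {
    tab <- subtype_by_age_table(subtypes$subtype, ag2)
    contrasts <- list(
      subtype_vs_age = categorical_contrast(tab$counts),
      sex_vs_age = categorical_contrast(table(eligible$sex, ag2))
    )
    list(subtype_by_age = tab, contrasts = contrasts)
  })

  assoc <- stage_wrap("associate", out_dir, {
    fm <- make_feature_matrix(filt$kept, cnv_calls$gene, cnv_calls$arm, ids)
    test_associations(fm, ag2 == "young", eligible$sex,
                      min_prev = min_prev, fdr_scope = fdr_scope,
                      fdr_cut = fdr_cut)
  })

  trends <- stage_wrap("trend", out_dir, {
    instability_vs_age(
      data.frame(tmb = scores$tmb, cis = scores$cis,
                 age = eligible$age, sex = eligible$sex),
      age_cutoff, age_breaks)
  })

  sigs <- stage_wrap("signatures", out_dir, {
    tl <- tally_motifs(filt$kept,
                       as.character(ag2)[match(filt$kept$sample_id, ids)])
    sim <- if (all(c("young", "old") %in% rownames(tl$counts)))
      cosine_sim(tl$counts["young", ], tl$counts["old", ])
    else NA_real_
    list(catalog = tl$counts, skipped = tl$skipped,
         young_old_cosine = sim)
  })

  summary <- list(
    package = "eogc",
    version = as.character(utils::packageVersion("eogc")),
    seed = if (simulated) config$seed else NA,
    simulated = simulated,
    thresholds = unclass(thresholds),
    min_purity = min_purity, min_prev = min_prev, fdr_cut = fdr_cut,
    age_cutoff = age_cutoff, age_breaks = age_breaks,
    counts = list(
      input_patients = nrow(inputs$clinical),
      eligible_patients = nrow(eligible),
      excluded_patients = nrow(cohort$excluded),
      young = sum(ag2 == "young", na.rm = TRUE),
      old = sum(ag2 == "old", na.rm = TRUE),
      candidate_variants = unname(filt$counts["input"]),
      kept_variants = unname(filt$counts["kept"]),
      filter_drops = as.list(filt$counts[c("blacklist", "repeats",
                                           "evidence")]),
      subtypes = as.list(table(subtypes$subtype))
    ),
    results = list(
      significant_features = assoc$feature[assoc$significant],
      n_significant = sum(assoc$significant),
      tmb_trend_z = trends$trends$z[trends$trends$score == "tmb"],
      cis_trend_z = trends$trends$z[trends$trends$score == "cis"],
      subtype_vs_age_p = tables$contrasts$subtype_vs_age$p_value,
      sex_vs_age_p = tables$contrasts$sex_vs_age$p_value,
      young_old_signature_cosine = sigs$young_old_cosine
    )
  )

  out <- list(inputs = inputs, cohort = cohort, filter = filt,
              scores = scores, cnv_calls = cnv_calls, subtypes = subtypes,
              tables = tables, associations = assoc, trends = trends,
              signatures = sigs, summary = summary)

  if (!is.null(out_dir)) {
    write_clinical(inputs$clinical, file.path(out_dir, "clinical.tsv"))
    write_variants(inputs$variants, file.path(out_dir, "variants.tsv"))
    write_variants(filt$kept, file.path(out_dir, "kept.tsv"))
    write_tsv(filt$audit, file.path(out_dir, "filter_audit.tsv"))
    write_tsv(cohort$excluded, file.path(out_dir, "cohort_exclusions.tsv"))
    write_tsv(scores, file.path(out_dir, "scores.tsv"))
    write_tsv(cnv_calls$gene, file.path(out_dir, "cnv_calls.tsv"))
    write_tsv(cnv_calls$arm, file.path(out_dir, "arm_calls.tsv"))
    write_tsv(subtypes, file.path(out_dir, "subtypes.tsv"))
    write_tsv(as.data.frame(tables$subtype_by_age$counts),
              file.path(out_dir, "subtype_by_age.tsv"))
    write_tsv(assoc, file.path(out_dir, "associations.tsv"))
    write_tsv(trends$trends, file.path(out_dir, "trends.tsv"))
    write_tsv(data.frame(group = rownames(sigs$catalog), sigs$catalog,
                         check.names = FALSE),
              file.path(out_dir, "catalog.tsv"))
    if (simulated) {
      truth <- inputs$truth
      truth$latent <- truth$carriers <- NULL
      jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

#' Read a pipeline configuration file
#'
#' YAML with either a `simulate:` block (arguments of
#' [simulation_config()]) or an `inputs:` block of file paths; optional
#' `thresholds:` and `analysis:` blocks override defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return List with `config`, `thresholds`, and `analysis` arguments
#'   ready for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    sim <- y$simulate
    if (!is.null(sim$subtype_probs))
      sim$subtype_probs <- unlist(sim$subtype_probs)
    config <- do.call(simulation_config, sim)
  } else if (!is.null(y$inputs)) {
    config <- y$inputs
  } else {
    stop_config("config needs a 'simulate' or 'inputs' block")
  }
  thresholds <- do.call(score_thresholds, y$thresholds %||% list())
  analysis <- y$analysis %||% list()
  list(config = config, thresholds = thresholds, analysis = analysis)
}
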