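# eogc

Age-stratified somatic alteration analysis for targeted gastric cancer
sequencing panels.

Early-onset gastric cancer (diagnosis before 45) carries a worse
prognosis than later-onset disease, and the somatic alterations enriched
in young patients are candidate explanations. `eogc` implements, as a
tested and reusable R pipeline, the analysis such a study runs on a
targeted panel cohort:

* **Somatic variant filtering** — panel-of-normals blacklist (drop when
  seen in >10% of normals), repeat-region removal, and evidence rules
  (COSMIC hotspot: >3 mutant reads & VAF ≥ 1%; otherwise >5 reads &
  VAF ≥ 2%).
* **Per-patient instability scores** —
  MSI score = fraction of 52 panel indel sites unstable (positive at
  ≥ 0.40); TMB = non-driver mutation count; gene CNV calls at
  |log2 depth ratio| ≥ 0.6; CIS = mean over autosomes 1–22 of the
  per-chromosome fraction of genes with |log2| > 0.2.
* **Molecular subtyping** — first-match cascade
  EBV → MSI (score ≥ 0.40) → CIN (CIS ≥ 0.25) → GS.
* **Age-enrichment statistics** — for every alteration prevalent in
  >5% of an age group, the sex-adjusted logistic model
  `logit P(young) = β₀ + β₁·alteration + β₂·sex`, with odds ratio
  `exp(β₁)`, Wald 95% CI, and Benjamini–Hochberg FDR (significant at
  FDR < 0.1); Cuzick rank trend tests of TMB and CIS over the age bins
  <45 / 45–54 / 55–64 / ≥65; chi-square or Fisher contrasts.
* **Mutational signatures** — 96-trinucleotide-motif catalogs
  (pyrimidine-centred convention) and multiplicative-update NMF with
  cosine-similarity signature matching.
* **Synthetic cohorts** — a generator with planted odds ratios, latent
  subtypes, and age trends, so the whole pipeline is testable and
  calibratable without access to restricted patient data.

See `vignettes/eogc-methods.Rmd` for the full model description and the
design decisions behind every threshold.

## Worked example

```r
library(eogc)

cfg <- simulation_config(n_patients = 5000, seed = 7)
res <- run_pipeline(cfg, out_dir = "run7")

unlist(res$summary$counts$subtypes)
#>  EBV  MSI  CIN   GS
#>  448  809 2116 1627

subset(res$associations, significant,
       select = c(feature, class, odds_ratio, ci_low, ci_high, fdr))
#>          feature    class odds_ratio    ci_low   ci_high          fdr
#> 1       CDH1_mut mutation  2.3417225 1.8368171 2.9854166 8.121030e-10
#> 4   20q_arm_gain      arm  0.4874544 0.3770273 0.6302244 1.062161e-06
#> 14    PIK3CA_mut mutation  0.4615215 0.3456342 0.6162645 9.888233e-06
#> 206   FGFR2_gain      cnv  1.5664763 1.2029633 2.0398363 1.158883e-03
#> 242     MYC_gain      cnv  0.6350974 0.4776741 0.8444016 2.164934e-03
#> ...

res$trends$trends
#>   score statistic        z       p_value degenerate
#> 1   tmb  37005488 25.98232 7.846060e-149  FALSE
#> 2   cis  36543498 21.70145 1.988066e-104  FALSE
```

The odds ratios are young-vs-old risks of each alteration, adjusted for
sex: the planted young-enriched CDH1-like mutation (true OR 2.5) and
FGFR2-like gain (true OR 2.0) come out enriched in the young group,
the planted old-enriched features below 1, and the positive trend
z-scores say TMB and CIS rise across the four age bins — older patients
are genomically less stable. `run7/` holds every intermediate table
(kept variants, filter audit, scores, subtypes, associations, trends,
motif catalog) plus `truth.json` (planted parameters) and
`summary.json`.

A thin command-line wrapper is installed at `inst/cli/eogc`:

```sh
Rscript inst/cli/eogc run-all --config cfg.yaml --out run_dir
```

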