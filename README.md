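# hccdriver

Multi-cohort driver-gene discovery and downstream biomarker evaluation for
staged liver disease, as a tested, reusable R pipeline.

## The problem

Hepatocellular carcinoma develops through an ordered ladder of liver states
— normal liver (NL) < chronic hepatitis (CH) < cirrhosis (LC) < dysplastic
nodule (DN) < early HCC (eHCC) < advanced HCC (aHCC). A convincing candidate
driver gene is (i) differentially expressed between tumor and non-tumor
tissue in *every* discovery cohort with a consistent direction, (ii) rises
*monotonically* along the stage ladder in every cohort, and (iii) survives
the same trend test in independent validation cohorts. hccdriver implements
this cascade and the analyses used to characterise a nominated driver:
gene-set enrichment in samples stratified by the driver's pseudo-bulk
expression, single-cell positivity proportions, promoter-methylation
biomarker evaluation (paired differential beta, ROC with DeLong intervals,
survival), and closed-form qPCR/qMSP quantification.

The statistical core, in the field's standard notation:

* **DEG gate**: per gene, Welch *t* on log2 expression; flag when
  BH-adjusted *p* < 0.05 and |log2 FC| ≥ log2 1.5.
* **Serial (trend) selection**: one-sided increasing Jonckheere–Terpstra
  statistic *J* = Σ<sub>i&lt;j</sub> U<sub>ij</sub> over ordered stage
  pairs (exact permutation enumeration for n ≤ 12, tie-corrected normal
  approximation otherwise), BH across genes, plus a near-monotone gate on
  stage means and a minimum rise of log2 1.5.
* **Enrichment**: weighted Kolmogorov–Smirnov running-sum ES (preranked,
  seeded gene-label permutations) and rank-based ssGSEA (exponent 0.25).
* **Biomarker**: AUC = P(tumor score beats non-tumor score) via the
  Mann–Whitney identity; Kaplan–Meier / log-rank / univariate Cox
  (Breslow ties) with HR = exp(β̂) and Wald 95% CI; 2^−ΔΔCt relative
  expression; qMSP ΔCt with derived fraction 1/(1 + 2^ΔCt); tumor volume
  0.52 × length × width².

Because the original inputs are external cohort accessions, the package
ships seeded generators that emit every input *with ground truth* (planted
monotone drivers, a known hazard ratio, a known methylation–expression
correlation), so recovery and calibration are measured, not assumed.

## Worked example

Generate eight staged cohorts sharing 50 planted drivers (0.5 log2 per
stage step, noise SD 0.5, 10 samples/stage), run the cascade with three
discovery and five validation cohorts, and score recovery:

```r
library(hccdriver)

sim <- generate_multistage_cohorts(n_cohorts = 8, seed = 1)
cascade <- run_cascade(sim$cohorts[1:3], sim$cohorts[4:8])
cascade
#> <driver_cascade>
#>   tier-A cohorts: 3, tier-B cohorts: 5
#>   consensus DEGs: 50
#>   tier-A trend consensus: 50 genes
#>   final list: 50 genes

head(tidy(cascade), 3)
#> # A tibble: 3 x 3
#>   gene   n_pass mean_z
#>   <chr>   <int>  <dbl>
#> 1 g00016      5   8.02
#> 2 g01111      5   7.92
#> 3 g01329      5   7.88

score_recovery(tidy(cascade)$gene, sim$truth)
#> # A tibble: 1 x 6
#>   n_listed n_drivers n_true_positive n_false_positive sensitivity null_pass_rate
#>      <int>     <int>           <int>            <int>       <dbl>          <dbl>
#> 1       50        50              50                0           1              0
```

All 50 genes in the final list are planted drivers (`sensitivity = 1`) and
no null gene leaked through (`null_pass_rate = 0`): the consensus DEG step,
the per-cohort trend gates and the require-all validation each behaved as
designed. The `mean_z` column is the average Jonckheere z-score across the
five validation cohorts and orders the list.

Downstream, a known hazard ratio is recovered with its confidence interval:

```r
surv <- generate_survival(n_per_group = 500, true_hr = 2, seed = 2)
cox_binary_hr(surv)
#> <hcc_coxfit> HR (high vs low) = 2.015 [1.727, 2.350],
#>   log-rank chi2 = 82.502 (p = 1.06e-19), n = 1000 (715 events)
```

File-based use mirrors the in-memory API: `run_workflow(run_config(...))`
executes the `simulate`, `discovery`, `enrichment` or `biomarker` pipeline
end to end, writing every intermediate table plus a provenance file;
identical configuration and seed give byte-identical output trees.

## Package layout

* `generate_*()` — seeded synthetic-data generators with ground truth
* `compute_de()`, `consensus_degs()`, `trend_score()`, `consensus_trend()`,
  `run_cascade()` — the discovery cascade
* `preranked_gsea()`, `ssgsea_score()`, `ora_hypergeometric()`,
  `compare_ssgsea_groups()` — enrichment
* `aggregate_expression()`, `stratify_quartiles()`,
  `positivity_proportion()` — single-cell pseudo-bulk
* `differential_methylation()`, `call_hypomethylation()`, `roc_auc()`,
  `methylation_expression_association()` — methylation biomarker
* `dichotomize()`, `km_estimate()`, `logrank_test()`, `cox_binary_hr()` —
  survival
* `ddct_fold_change()`, `qmsp_relative_methylation()`, `tumor_volume()` —
  assay quantification
* `read_*()`/`write_*()`, `run_config()`, `run_workflow()` — file formats
  and orchestration

The methods vignette (`vignettes/driver-discovery-methods.Rmd`) documents
the models, the defaults and the design decisions in detail.
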