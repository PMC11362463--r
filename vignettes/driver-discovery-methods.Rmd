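---
title: "Methods: multi-cohort driver-gene discovery and downstream characterisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort driver-gene discovery and downstream characterisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hccdriver)
```

## The problem

Hepatocellular carcinoma develops through an ordered sequence of liver
states: normal liver (NL), chronic hepatitis (CH), cirrhosis (LC),
dysplastic nodules (DN), early and advanced carcinoma (eHCC, aHCC). A
candidate driver gene should not merely differ between tumor and non-tumor
tissue; its expression should climb monotonically along this ladder, and it
should do so consistently in independent cohorts. hccdriver implements that
discovery cascade as reusable, tested code, together with the downstream
analyses used to characterise a nominated driver: gene-set enrichment in
samples stratified by the driver's pseudo-bulk expression, a single-cell
positivity statistic, promoter-methylation biomarker evaluation (paired
differential beta values, ROC, survival), and closed-form qPCR/qMSP
quantification.

Because the original cohorts are external accessions, the package validates
itself on synthetic data with planted signal: every generator emits its
ground truth, so sensitivity, specificity and calibration are measurable
quantities rather than hopes.

## The discovery cascade

`run_cascade()` chains three stages.

**1. Per-cohort differential expression.** For each discovery ("tier-A")
cohort, `compute_de()` contrasts tumor stages (default eHCC + aHCC) against
non-tumor stages (NL + CH + LC) with a per-gene Welch t-test on log2
expression, BH adjustment across genes, and the conventional gate: adjusted
p below `alpha` (0.05) **and** absolute fold change of at least
`fc_threshold` (1.5, i.e. |log2 FC| >= log2 1.5). DN sits between the tiers
biologically and is excluded from the contrast by default; both stage sets
are arguments. `consensus_degs()` keeps genes flagged in *every* cohort with
the *same direction* — the strictest reading of cross-cohort consistency,
and the one we adopt.

**2. Monotone trend selection.** The published analysis clustered stage
profiles and hand-picked "increasing" clusters. Graph-based profile
clustering is stochastic and its tuning is rarely reported, so the package
replaces it with a deterministic per-gene criterion that encodes the same
selection property. `trend_score()` requires all of:

* a one-sided increasing **Jonckheere–Terpstra** test across the cohort's
  ordered stages, BH-adjusted across the scored genes (`q < alpha`). The
  test uses exhaustive permutation enumeration when the cohort has at most
  12 samples and the tie-corrected normal approximation otherwise;
* **near-monotone stage means**: each consecutive stage-mean step may dip by
  at most `tolerance` times the gene's overall rise (last minus first stage
  mean, floored at zero). Scaling the allowance by the gene's own rise keeps
  the gate scale-free: a gene climbing 2.5 log2 units may dip 0.25 between
  adjacent stages at the default `tolerance = 0.1`, while a flat gene gets
  no allowance at all. We deliberately did not scale the allowance by the
  residual SD: with realistic noise (stage-mean SE near 0.16 log2 at 10
  samples/stage and SD 0.5) an SD-scaled slack small enough to look strict
  either rejects a substantial fraction of genuinely monotone genes once
  five or more stage steps and eight cohorts are intersected, or degenerates
  into no gate at all;
* a **span gate**: the overall rise must reach `span_min` (log2 1.5), so
  statistically "significant" but biologically negligible trends are
  dropped.

**3. Cross-cohort trend consensus and validation.** `consensus_trend()`
intersects the per-cohort passes (all cohorts by default; a quorum is
available) and orders survivors by mean Jonckheere z-score, ties broken
lexicographically. The tier-A survivors are then re-scored in every
validation ("tier-B") cohort, again requiring a pass everywhere. The final
list is deterministic given the inputs and invariant to gene-row and
sample-column order.

## Downstream characterisation

**Stratified enrichment.** `aggregate_expression()` sums raw single-cell
counts per sample (pseudo-bulk; totals are conserved), and
`stratify_quartiles()` splits samples by the focal gene's aggregated value:
top ceiling(n/4) samples are "high", bottom floor(n/4) "low", remainder
"mid". We read "1st quartile" as the *highest*-expression quartile — the
group-name semantics (high/mid/low) leave no other coherent reading — and
use the nearest-rank rule so the partition is exact for every n. DE between
high and low strata on log2 CPM feeds `rank_genes_by_log2fc()` (descending
log2 FC, lexicographic ties) and `preranked_gsea()`, the classic weighted
Kolmogorov–Smirnov running sum (weight 1, hit increments proportional to
|score|^weight, miss decrements 1/(N−hits)); p-values come from seeded
gene-label permutations because the input is a preranked list, and the NES
divides by the mean |permuted ES| of matching sign (absent below 10
matching-sign permutations). `ssgsea_score()` is the rank-based
single-sample score (canonical exponent 0.25, raw scores by default with a
range-normalisation flag), and `compare_ssgsea_groups()` applies the
Wilcoxon rank-sum test per gene set between high and low strata with BH
across sets. `positivity_proportion()` implements the count-threshold rule:
a cell is positive at count >= 1, and the proportion divides by all cells of
the phenotype.

**Methylation biomarker.** `differential_methylation()` runs a paired
t-test of tumor minus non-tumor beta per CpG with BH across CpGs.
`call_hypomethylation()` flags a patient when the tumor beta falls below the
paired non-tumor beta by more than `margin` (default 0 — strict paired
comparison; a threshold-based dichotomization is available separately
through `dichotomize()`, since the published dichotomization rule is not
stated). `roc_auc()` uses the Mann–Whitney identity with half credit for
ties and a DeLong 95% interval; the tumor class is positive, and the
`lower_is_positive` flag makes the hypomethylated-marker orientation
explicit instead of silently reporting 1 − AUC.

**Survival.** `km_estimate()`, `logrank_test()` and `cox_binary_hr()` wrap
the survival package (product-limit, O−E with hypergeometric variance, and a
univariate Cox fit with Breslow ties — Efron behind a flag — iterated to a
1e-9 tolerance). The median split sends ties to the low group; complete
separation is a hard error rather than a divergent estimate. External-cohort
hazard ratios are not reproducible from synthetic data, so this module is
validated by simulation coverage: the Wald 95% interval of a simulated
hazard ratio of 2 covers the truth at the nominal rate (measured ~0.95).

**Assay quantification.** `ddct_fold_change()` averages replicate Ct values
on the cycle scale (standard practice for the 2^−ddCt method), then forms
dCt, ddCt against the reference sample, and 2^−ddCt.
`qmsp_relative_methylation()` reports the methylated-minus-unmethylated Ct
difference — the assay's stated quantity — plus a clearly-labelled derived
two-species fraction 1/(1 + 2^dCt). `tumor_volume()` is the ellipsoid
approximation 0.52 x length x width^2 with a warn-and-swap convention when
width exceeds length.

## The synthetic-data generators

All generators are pure functions of their arguments including the seed
(sub-streams are derived deterministically per cohort or table), and each
returns its ground truth.

* `generate_multistage_cohorts()` — Gaussian noise on the log2 scale
  (log-normal intensities, matching the microarray-style data the cascade
  consumes); drivers gain `per_stage_shift` (default 0.5 log2) per stage
  step, nulls are stage-constant; cohorts share driver identities but
  differ by an additive batch shift (SD 0.3 log2) and noise realisation.
  Defaults — 6 stages, 2000 genes, 50 drivers, noise SD 0.5, 10
  samples/stage — are the study conditions under which recovery is
  evaluated (3 discovery + 5 validation cohorts).
* `generate_sc_counts()` — negative binomial counts with log-normal
  per-cell size factors, the standard overdispersion model; the resulting
  dropout exercises the positivity rule. The focal gene (and an optional
  co-regulated module) scales with phenotype, so stratified enrichment can
  be validated end to end.
* `generate_methylation_expression()` — beta values are truncated Gaussian
  on the beta scale (SD `noise_sd`, clamped to (0, 1)). We chose this over a
  Beta-distribution draw so the paired hypomethylation fraction has the
  exact closed form pnorm(drop / (noise_sd * sqrt(2))), giving the calling
  rule an analytic oracle; at the default mean (0.7) and SD (0.1) the
  truncation mass is negligible. Expression is coupled to the first marker
  CpG's tumor beta so the achieved Pearson correlation approximates
  `target_r` (inverse by construction; positive targets are rejected).
* `generate_survival()` — exponential event times with hazard
  baseline x HR^group and independent exponential censoring.
* `generate_ct_table()` — Ct values built so the noiseless 2^−ddCt
  computation inverts the programmed fold changes exactly.

What the generators do **not** emulate: platform-specific microarray
artifacts, batch effects that need correction, doublets or ambient RNA,
Beta-value heteroscedasticity near the support boundaries, and non-
proportional hazards. Passing tests therefore demonstrate that the
*algorithms* behave as specified under their stated models, not that any
particular biological dataset will yield a particular gene list.

## Numerical choices and degenerate inputs

* Two-sided tests by default; the test-selection policy
  (`choose_and_run_group_test()`) screens each group with Shapiro–Wilk at
  alpha 0.05 (conventional; unstated in the source analyses) and then takes
  Welch t / paired t / ANOVA + Tukey, or Wilcoxon / Kruskal–Wallis + Dunn
  with BH (the Dunn adjustment is likewise a package convention).
* Rank tests use midranks with tie-corrected variances; the Wilcoxon switch
  to exact enumeration happens at min(n) <= 8 on tie-free data.
* Constant inputs are explicit: correlation on a constant vector and a
  median split of identical values are errors; identical groups in rank
  tests return p = 1 by convention rather than NaN.
* All permutation procedures take a seed and are byte-reproducible;
  workflow reruns with the same configuration produce byte-identical
  output trees (no timestamps in provenance).
* Problem sizes used by the test-suite property checks (2000 genes, 8
  cohorts, 2000 null replicates for calibration, 500 replicates for Cox
  coverage) were chosen to keep Monte-Carlo error well below the asserted
  margins while remaining comfortable on a single CPU.

## Known limitations

The cascade assumes normalized log2 expression on input — probe collapsing
and normalization are out of scope. Gene sets are flat lists (no GO-graph
propagation). The Cox module is univariate by design; multivariable models,
time-varying covariates and competing risks are out of scope. The
preranked-GSEA permutation scheme permutes gene labels, which is the
appropriate null for a preranked list but not identical to phenotype
permutation in the original desktop tool.
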