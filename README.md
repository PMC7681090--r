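# cfrs — cfDNA copy-number response score and ctDNA VAF monitoring

`cfrs` is an R package for asking, from a baseline liquid biopsy, *which
lung cancer patients will respond to platinum-doublet chemotherapy* — and
for tracking, from a second blood draw at treatment cycle 2, *whether a
given patient is in fact responding*. It is aimed at biostatisticians and
translational researchers working with gene-level cell-free DNA (cfDNA)
copy-number profiles and panel-based circulating tumor DNA (ctDNA) variant
calls.

## The method

**Response score (RS).** Let `x_ij` be the log2 copy ratio of gene *j* in
patient *i*, and let the binary outcome be responder (best response CR/PR)
vs non-responder (SD/PD). On a training cohort:

1. *Consensus filter.* Every gene is scored by seven between-group
   criteria: absolute standardized mean difference (|Cohen's *d*|),
   mutual information of the loss/neutral/gain categorization with the
   outcome (permutation p), folded per-gene AUC, and the p-values of the
   chi-square, Wilcoxon rank-sum, one-way ANOVA and pooled t tests. A gene
   "votes" once per criterion passed; genes with ≥ 4 votes survive.
2. *Penalized fit.* Surviving genes enter an L1-penalized logistic
   regression on standardized values; the penalty λ is chosen by
   stratified cross-validated classification accuracy (ties → sparser
   model). The per-patient score is the coefficient-weighted sum

   RS_i = Σ_j β_j · (x_ij − μ_j) / σ_j

   with μ, σ frozen from training.
3. *Dichotomization.* The cutoff is the accuracy-optimal threshold over
   all midpoint candidates (ties → maximal Youden J); `RS > cutoff` is the
   high-RS group. Cutoff and standardization are reused unchanged on
   validation data.

High vs low RS groups are then compared by objective response rate
(chi-square / Fisher), and by progression-free and overall survival
(Kaplan–Meier, log-rank, Cox hazard ratio). Quantile-cutoff screens of
TMB, cfDNA concentration, ctDNA fraction and maximum VAF provide the
negative controls.

**VAF monitoring.** Per patient and timepoint, detected variants
(VAF ≥ LOD, sufficient alt reads) are summarized to a mean VAF; the
paired change baseline→cycle 2 is tested within response groups, and
cycle-2 *detectability* (any variant left?) is associated with response
and PFS.

Because the underlying trial's patient-level data are not public, the
package ships a seeded generator ([`simulate_cohort()`]) producing
cohorts with the statistical structure the analysis assumes — two arms
(LP/GP ≈ 80/75 of 155), ~60% responders, a 31-gene copy-number effect
set, response-coupled exponential survival, and VAF trajectories that
shrink in responders and grow in non-responders — so the entire pipeline
is testable end to end.

## Worked example

```r
library(cfrs)
cohort <- simulate_cohort(sim_config(seed = 7))
res <- run_full_analysis(cohort, "run7", seed = 7)
cat(readLines("run7/summary.md"), sep = "\n")
```

prints

```
# Analysis summary

- cohort: 155 patients (101 training / 54 validation)
- consensus-selected genes (>= 4 votes): 40
- model genes after L1 fit: 23 (lambda = 0.04462)
- RS cutoff: -0.49902 (training accuracy 1.000)
- training ROC AUC: 1.000 | validation ROC AUC: 1.000
- training ORR high vs low: 100.0% vs 0.0% (p = 9.2e-24)
- validation ORR high vs low: 100.0% vs 0.0% (p = 2e-13)
- C2 undetectable vs detectable: ORR 91.2% vs 20.0%, PFS HR 0.58
```

Reading the output: 40 of the 131 panel genes pass the ≥ 4-vote consensus
filter and the L1 fit keeps 23 of them. At the default planted effect size
(Cohen's *d* = 1.0 on 31 genes) the score separates responders essentially
perfectly on held-out patients — real cohorts, with weaker and correlated
signal, sit lower. Patients whose ctDNA is undetectable at cycle 2 have a
far higher response rate (91% vs 20%) and roughly half the progression
hazard (HR 0.58), the monitoring arm's expected signature. All artifacts
(`feature_stats.tsv`, `rs_model.json`, `rs_scores.tsv`,
`evaluation_report.tsv`, `km_curves.tsv`, `biomarker_screen.tsv`,
`vaf_summary.tsv`, `vaf_monitoring_report.tsv`, `manifest.json`) land in
the run directory; rerunning with the same seed reproduces them
byte-for-byte.

A command-line wrapper is installed at `exec/cfrs` inside the package
library:

```sh
Rscript "$(Rscript -e 'cat(find.package("cfrs"))')/exec/cfrs" \
    run-all --simulate yes --seed 7 --outdir run7
```

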