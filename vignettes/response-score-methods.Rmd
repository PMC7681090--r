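---
title: "Methods: the copy-number response score and VAF monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the copy-number response score and VAF monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its statistical machinery:
the model behind the response score (RS), the assumptions baked into the
synthetic cohort generator, the numerical conventions, and the places
where the design was genuinely open and a choice had to be made.

## The problem

Advanced lung squamous carcinoma is still treated first-line with
platinum-doublet chemotherapy, and roughly 40% of patients do not
respond. The package operationalizes two liquid-biopsy ideas: (i) a
*baseline* predictor — a score built from gene-level cfDNA copy-number
log2 ratios that separates eventual responders (CR/PR) from
non-responders (SD/PD); and (ii) an *early monitoring* readout — the
change in ctDNA variant allele frequencies (VAF) between baseline and
treatment cycle 2.

## The consensus feature filter

For each gene the training cohort yields seven criterion statistics
(`compute_feature_stats()`):

| criterion | statistic | pass rule (default) |
|---|---|---|
| deviation | absolute standardized mean difference (pooled, n−2 denominator) | ≥ 0.5 |
| mutual information | MI in bits of the loss/neutral/gain × outcome joint | permutation p < 0.05 |
| AUC | folded Mann–Whitney AUC, ties ½ | ≥ 0.6 |
| chi-square | category × outcome table, no continuity correction | p < 0.05 |
| Wilcoxon | rank-sum, normal approximation, midranks, tie-corrected variance | p < 0.05 |
| ANOVA | one-way across the two outcome classes | p < 0.05 |
| t-test | two-sample, pooled variance | p < 0.05 |

Genes passing at least `min_votes = 4` criteria survive. Three of these
choices deserve comment:

* **"Deviation"** is not a uniquely defined term; we take it as
  |Cohen's *d*| because it is the only scale-free between-group deviation
  measure commensurate with the other criteria, and make its threshold a
  parameter (`d_min`).
* **MI and AUC carry no p-value by themselves**; MI gets a
  label-permutation p-value and AUC a fixed folded threshold so that
  "significantly different signal" is operational for all seven criteria.
* **With two outcome classes, ANOVA is the pooled t-test** (F = t²), so
  those two votes always move together. We keep both criteria for
  fidelity to the seven-criterion design, but this makes the filter
  *less* selective than seven nominally independent 5%-level tests would
  be: a gene that clears the t-test gets two votes at once, and the
  Wilcoxon is almost perfectly correlated with the t-test on
  near-Gaussian data. Under a pure null (no effect, n = 150, default
  thresholds) the measured fraction of genes reaching 4 votes is about
  3% rather than the ≪ 5% a naive multiplication would suggest; the
  filter's real stringency therefore comes from the interplay of the
  *non*-p-value criteria (deviation and AUC thresholds bind harder as
  n grows). No multiple-testing correction is applied inside the filter —
  its purpose is consensus ranking, not inference.

The MI permutation p is computed by drawing the shuffled category ×
outcome tables directly from their multivariate hypergeometric
distribution (margins fixed), which is distributionally identical to
shuffling labels, makes the p-value invariant to sample reordering, and
vectorizes.

Per-criterion α is 0.05; the chi-square categorization uses ±0.2 log2
units (a common shallow-WGS convention for gene-level gains/losses),
strict inequalities, boundary values neutral. A gene on which a criterion
is undefined (e.g. a constant column) simply fails that criterion.

## The penalized score

Surviving genes enter an L1-penalized logistic regression (glmnet) on
training-standardized values. Conventions:

* **Penalty grid**: the 50-value path glmnet computes on the training
  data; **fold assignment**: stratified by outcome, seeded.
* **Selection rule**: λ maximizing mean cross-validated classification
  accuracy at probability 0.5. Accuracy ties break toward the larger
  (sparser) λ *among penalties whose full-data refit retains at least one
  gene* — a maximally sparse tie-winner with an empty refit would be a
  useless model, and a grid whose every solution is empty raises an
  explicit error instead.
* **The score** is the linear predictor without intercept,
  `RS = Σ β_j x̃_j`; the decision cutoff absorbs the constant. An
  alternative reading — add each selected gene's coefficient only when
  the gene is copy-number altered in that sample — is available as
  `compute_rs(..., mode = "altered_sum")`; it produces a step-valued
  score and is provided for comparison, not as the default, because only
  the weighted sum yields a continuous ROC.
* **Leakage control**: standardization statistics and the cutoff are
  functions of training samples only and are frozen into the serialized
  model; the run manifest records them so this can be audited.
* **Cutoff**: candidates are midpoints of adjacent distinct scores plus
  ±∞ sentinels; maximize accuracy, break ties by Youden J, then by the
  smallest candidate. If the *reversed* rule would be strictly more
  accurate the result is flagged `inverted_separation` rather than
  silently flipped — a predictor that separates backwards should be seen
  to do so.
* The train/validation split is stratified by outcome at
  `split_fraction = 0.65` (unstated in the source design; stratification
  preserves class balance in both halves).

Whether the original algorithm fed the filter and LASSO continuous or
categorized copy numbers is not recoverable; we use continuous values
(they support all seven criteria and a continuous ROC) and note that a
user can fit on a −1/0/1 coding by categorizing first.

## Outcome statistics

ROC curves are traced over all distinct thresholds; the trapezoid AUC
equals the tie-aware rank AUC to numerical precision and both are
reported. Response rates are compared by chi-square without continuity
correction, switching to two-sided Fisher when any expected count is
below 5 (the rule actually used is recorded per result, and either test
can be forced). Survival uses the survival package: Kaplan–Meier with the
event-before-censor tie rule, median defined as the first time
S(t) ≤ 0.5; the two-group log-rank; Cox with Breslow ties, Wald CI and
p. Hazard ratios are accompanied by the crude O/E-ratio estimate, since
an HR can be quoted from either. A monotone partial likelihood is flagged
`unbounded` rather than reported as a huge finite HR. The quantile
biomarker screen dichotomizes at the 25th/50th/75th percentiles and
reports ORR and log-rank p-values per cutoff, flagging degenerate splits.

## VAF monitoring

A variant is *detected* iff VAF ≥ `lod` (default 0.1%) and
`alt_reads ≥ 3` — representative ultra-deep panel sensitivity, both
configurable. The per-sample summary is the mean VAF over detected
variants (`mode = "max"` selectable); mean is the default because it is
less dominated by one outlier variant. Patients with no detectable
baseline signal have an undefined change and are excluded from the
paired analysis (and listed in a drop log). The paired t-test is
two-sided within each response group; a group whose deltas are
identically zero is reported degenerate with p = 1, never spuriously
significant. Cycle-2 detectability splits patients for the ORR
comparison, log-rank and Cox HR (undetectable relative to detectable).

## The synthetic cohort generator

`sim_config()` defaults encode the cohort structure the analysis
expects; each was fixed once, before any testing, on field-typical
grounds:

* **Cohort**: 155 patients, LP:GP ≈ 80:75, responder rate 93/155 ≈ 60%,
  CR rare among responders (2%), SD:PD ≈ 45:55 among non-responders.
* **CNV**: per-gene log2 ratios N(0, 0.25²) — the dispersion seen in
  shallow cfDNA profiling after gene-level summarization; responders
  shifted by `effect_size × noise_sd` on the 31 effect genes, sign fixed
  by hashing the symbol so gains and losses both occur; default
  `effect_size = 1.0` (a strong but attainable per-gene effect, chosen so
  that recovery is a meaningful test rather than a coin flip); 100 null
  genes by default.
* **Survival**: exponential PFS with medians 230 d (responders) vs 95 d
  (non-responders) — these bracket the ~150-day all-comers median at a
  60% responder rate; OS = PFS + an exponential tail of median 190 d, so
  OS ≥ PFS holds by construction and censoring propagates from PFS;
  20% uniform censoring.
* **Variants**: per patient, a zero-truncated Poisson(5) count of
  baseline variants on a 29-gene panel (a synthetic stand-in list of
  common lung drivers); baseline VAF lognormal(log 0.02, 0.8) — median
  2%, 95% range roughly 0.4–10%; read support binomial at depth
  ~15,000×. Cycle-2 VAF = baseline × group factor (0.3 responders, 1.5
  non-responders) × lognormal(0, 0.4) per-variant jitter. With
  probability 0.8 (responders) / 0.1 (non-responders) a patient's
  cycle-2 variants clear below the detection limit entirely; without
  such a clearance mechanism essentially no patient would ever become
  undetectable, and the detectability analysis would have nothing to
  measure.

What the generator deliberately does **not** emulate: correlated
copy-number segments (genes are independent), tumor purity and clonal
structure, batch effects, inter-gene VAF correlation within a patient,
and non-exponential hazards. Passing tests therefore demonstrate that the
pipeline recovers planted structure of the assumed form — not that real
cfDNA data carry such structure.

## Numerical conventions and degenerate inputs

Strict inequalities at every dichotomy (categorization boundaries are
neutral; a score equal to the cutoff is "low"); permutation p-values use
the add-one rule (1 + #extreme)/(n + 1); all randomness flows from one
root seed expanded by fixed stage offsets, and reruns are byte-identical
(for that reason the run manifest carries no timestamps). TSV writers
emit enough digits that reading back reproduces doubles exactly.
Constant genes collect zero votes; constant biomarkers flag every screen
row degenerate; a constant covariate or an event-free group is an error
naming the culprit.

## Problem sizes used by the test-suite

The property tests run at sizes where their claims are sharp: oracle
equivalences on hundreds of instances of n ≤ 50; null calibration at
n = 150 with 100 genes × 20 seeds and 500 association replicates;
parameter recovery on 155-patient cohorts (100 training / 55 held out,
31 effect + 120 null genes) over 20 seeds; hazard-ratio recovery at
n = 300 over 20 seeds; monitoring contrasts on 80-patient cohorts over
100 seeds. The log-rank analytic-vs-permutation comparison is run at
n = 60, where the chi-square approximation is expected to sit within
Monte-Carlo error of the exact permutation distribution; at very small n
the two differ systematically, which is a property of the approximation,
not a defect of either computation.

## Known limitations

The 31-gene effect set is used as simulator ground truth, not a claim
that these genes are re-derivable: recovering the original set would
require the original patient-level data. The consensus filter's null
selection rate (~3% at n = 150, see above) is a structural consequence
of the duplicated ANOVA/t vote and correlated criteria. Single-covariate
Cox only; no competing risks; no probability calibration of the score;
VAF monitoring assumes variant identity is stable across timepoints and
ignores clonal hematopoiesis.
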