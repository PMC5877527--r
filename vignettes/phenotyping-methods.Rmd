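---
title: "Methods: integrated clinical-metabolomic phenotyping of COPD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated clinical-metabolomic phenotyping of COPD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chronic obstructive pulmonary disease (COPD) is clinically heterogeneous, and
the GOLD A-D consensus categories stratify patients by symptoms and
exacerbation risk rather than by molecular pathology. A natural question is
whether an *integrated* view — clinical and demographic variables, absolutely
quantified serum metabolites (amino acids, biogenic amines, acylcarnitines,
glycerophospholipids, sphingolipids, hexose), and untargeted mass-spectrometric
profiles of serum and exhaled breath condensate (EBC) — supports a de novo,
data-driven phenotyping of COPD that is at least as coherent as the GOLD
stratification. `metaphen` implements that analysis end to end: five-block
data integration, univariate and multivariate statistics, hierarchical
clustering scored by a battery of cluster-validity indices, and an acceptance
rule that compares every candidate clustering against a GOLD-based positive
control. Because raw patient-level data of this kind are generally not
deposited, the package ships a synthetic-cohort generator whose defaults
encode the study conditions the pipeline is designed for, with planted,
recoverable effects, so that every stage is testable.

## Data integration

Six feature blocks are mapped to the unit interval and concatenated:

* **Untargeted spectra** (serum/EBC x positive/negative ionization). Peak
  lists acquired over 90-1400 Da are binned to a 1 Da grid (1311 bins,
  round-half-up), normalized to the total ion count (TIC) so each spectrum
  sums to one, log-transformed with a pseudocount (`ln(x + 1e-6)`), and mapped
  to (0,1) by the logistic transform `1/((0.5 + e^(-x)) * 2)`, equivalently
  `1/(1 + 2 e^(-x))`, which satisfies `f(0) = 1/3` and `f(ln 2) = 1/2`.
* **Clinical/demographic and targeted-metabolite variables** are divided by
  their per-variable maximum; dichotomous variables are 0/1 indicators first
  (max-scaling is then the identity).

TIC normalization removes multiplicative spectrum-level batch variation by
construction (it is scale-invariant and idempotent); binning conserves total
intensity.

Several compositional details are not derivable from first principles and are
fixed here as package decisions: bin assignment is round-half-up; the natural
log with pseudocount 1e-6 is used (no base or zero-handling is canonical);
the spectral transform order is bin -> TIC -> log -> logistic; zero bins are
retained so feature sets align across subjects. One consequence worth knowing:
TIC fractions are at most 1, so their logs are negative and the logistic
transform maps them to approximately `fraction/2`. Spectral features therefore
occupy a much narrower numeric range than max-scaled clinical or targeted
variables, and in synthetic cohorts the clinical block tends to dominate the
leading principal component. With instrument-scale intensities whose logs
straddle zero the same transform spreads spectral features across (0,1); the
block-contribution accounting (`block_contribution()`) makes this visible
rather than hiding it.

## Statistics

* `volcano()`: per-feature two-sample Student's t-test (pooled variance;
  Welch behind a flag) with the mean difference on the transformed scale as
  the effect axis. Ratio-type fold changes are avoided because the integrated
  scale has values near zero. Raw p-values are reported by default (matching
  the convention of the analyses this package reproduces); a
  Benjamini-Hochberg column is optional.
* `anova_tukey()`: one-way ANOVA across GOLD strata with Tukey HSD post hoc
  comparisons (studentized range, Tukey-Kramer standard errors), and the
  p < 0.0001 vs 0.0001-0.05 significance tiers used for reporting.
* `association_table()`: patients-only associations — Pearson r against
  continuous variables, pooled t-tests against dichotomous ones, ANOVA for
  multi-level ones (exacerbation counts are treated as a factor; their
  handling is not canonical). Cells with `|r| >= 0.49` or `p < 0.05` are
  flagged notable.
* `sensitivity_rerun()`: re-runs the volcano comparison after excluding
  subjects (e.g. all females, who occur only among controls in the emulated
  design) and reports the retained fraction of originally significant
  features.

## PCA and sparse PLS-DA

`pca_fit()` is a centered (unscaled — features already live on [0,1]) SVD
with a deterministic sign convention (largest-magnitude loading entry
positive). `block_contribution()` attributes `100 * sum(loading^2)` per block
and component; loadings are unit-norm, so each component's contributions sum
to 100%.

`splsda_fit()` is written from first principles: classes are dummy-coded and
centered; per component the leading singular-vector pair of the
cross-covariance between the deflated data and class matrix is computed, and
the data-side loading is hard-thresholded to retain exactly `keepX`
largest-magnitude entries (ties to the lower index) before renormalization
and deflation. The selection-count semantics are the contract; the
penalty-calibration path of reference implementations is not replicated,
though with `keepX = p` and one component the direction coincides with the
dense PLS-DA solution (verified against both a direct SVD oracle and
mixOmics in the tests). `splsda_tune()` uses repeated stratified k-fold
cross-validation — 10 repeats of 5 folds by default, the protocol this
pipeline standardizes on — scoring by balanced error rate (BER) of
nearest-class-centroid assignment in score space; ties prefer fewer
components, then smaller `keepX`. Classes smaller than the fold count fall
back to leave-one-out within the class.

## Cluster validity

Hierarchical clustering uses euclidean distance with complete linkage (merge
heights are then non-decreasing); trees are cut with `cut_k()` and partitions
are scored by `validity_report()`, which implements each index from its
definition: Calinski-Harabasz pseudo-F, Davies-Bouldin, the Baker-Hubert
adaptation of Goodman-Kruskal's gamma, the Hubert-Levine C-index, Rousseeuw's
mean silhouette, the Dunn index, the entropy of the membership distribution,
average/maximal within- and between-cluster distances, and (optionally) the
average proportion of non-overlap (APN) under leave-one-feature-out
re-clustering. Where the literature admits variants, the package pins one:
the C-index uses the sum of the `l` smallest/largest pairwise distances with
`l` the number of within-cluster pairs; Dunn uses single-linkage separation
over maximal diameter; entropy uses natural logs; APN deletes one feature
column at a time; singleton silhouettes are zero. Degenerate cuts (`k = 1`,
`k = n`) report the affected indices as `NA` with a reason, and a
zero-diameter partition reports `dunn = Inf`. All indices are checked against
brute-force pairwise-loop oracles in the test suite.

## The de novo phenotyping workflow

`enumerate_datasets()` builds 24 candidate datasets: the cross-product of
cohort scope (all subjects / COPD only), representation (original features /
principal components explaining at least 5% of variance, recomputed per
subset), and six block subsets (all; clinical; targeted; serum profiles; EBC
profiles; all metabolomic blocks). Each dataset is clustered once and cut at
k = 2..8 (the battery's optimum in comparable analyses has been reported
around six, so the range leaves headroom).

The **positive control** fits an sPLS-DA model with the GOLD strata as labels
(controls as a fifth class when in scope; the 2-component, 60-variables-kept
protocol split as 30 + 30) and evaluates the label partition in the resulting
score space with the same validity battery. Two points here were genuinely
open and are package decisions:

* The control model is always fit on the dataset's *source-subset original
  features*, even when the de novo arm clusters a PC representation. A
  supervised model fit on a handful of PC scores cannot represent the GOLD
  labels at all and would be a vacuously weak quality bar; the PC compression
  belongs to the clustering arm, not to the control.
* Evaluating the GOLD partition in raw dataset space is available as
  `space = "raw"` for comparison.

`accept_dataset()` accepts a candidate dataset when:

a. for at least one cut, all six *scale-free* geometry indices
   (Calinski-Harabasz, Davies-Bouldin, gamma, C-index, silhouette, Dunn) are
   within a relative tolerance (default 10%) of the positive control or
   better. Membership entropy grows with k and the raw distance summaries and
   APN are space- and scale-bound, so they are reported but not compared
   across the two spaces.
b. when controls are in scope, the k = 2 cut misclassifies at most two
   subjects against the COPD/control labels (the "branch out at the highest
   level" rule).
c. the chosen cut shows cluster structure beyond chance: its
   Calinski-Harabasz statistic must exceed, by at least three reference SDs,
   the distribution obtained by independently permuting every feature column
   (which preserves all marginals but destroys multivariate structure) and
   re-clustering. Without this guard, any dataset whose positive control
   cannot overfit (clinical-only, EBC, low-dimensional PC scores) would let
   chance clusterings through; with it the rule is two-sidedly calibrated —
   structureless cohorts accept nothing, strongly planted subtype structure
   is accepted and recovered.

`run_workflow()` orchestrates all of this and ranks datasets by their mean
relative oriented gap to the control; `write_workflow()` exports the summary
table, the full validity table, Newick dendrograms and a human-readable
acceptance report.

## The synthetic-cohort generator

Defaults encode the emulated study conditions: 25 COPD patients (all male;
GOLD A-D split 2/2/4/17; 40%/56%/4% current/ex/never smokers; published
comorbidity and medication prevalences) and 21 healthy never-smoker controls
(9 M / 12 F). Continuous clinical variables are truncated normals
moment-matched to the published medians and IQRs (log-normal pack-years;
negative-binomial exacerbation counts); COPD subjects always satisfy
FEV1/FVC < 0.7. Targeted analytes are log-normal around conventional serum
concentrations (analyte-level means are not published, so locations are
conventional rather than calibrated) with log-scale SD 0.3. Planted effects
are standardized log-mean shifts; the defaults (0.8-1.5 SD, configurable)
encode the qualitative signatures the pipeline should recover: sphingomyelins
and SM(OH) down in COPD, PUFA-phosphatidylcholines (total acyl C36-C40, >= 2
double bonds) down, lysoPCs up; lysoPCs additionally high in GOLD A,
kynurenine in GOLD B, putrescine up / ornithine down in GOLD C; serum-negative
m/z 327/367/368 shifted between groups, 1069/1317 high in GOLD B,
serum-positive 259 high in GOLD A. Untargeted spectra are synthetic peak
lists on a shared 400-peak grid per channel with heavy-tailed base
intensities, per-peak log-noise (SD 0.4), and a per-spectrum batch factor
`exp(N(0, 0.5^2))` that TIC normalization must remove; EBC channels carry no
group signal by default. An optional latent subtype structure
(`subtype_k`, `subtype_effect`) splits the COPD arm into balanced classes
with disjoint marker sets in the targeted panel and dedicated serum-negative
m/z markers — the ground truth for workflow-recovery experiments.

`null_cohort_config()` produces a genuinely structureless cohort for
calibration: both arms share the control clinical distributions, everyone is
a male never-smoker without flags, and the effect table is empty. Note that a
*default* cohort is not a null even with an empty effect table: the clinical
distributions of patients and controls differ by design, which is real
structure.

What the generator does **not** emulate: chromatography, isotope patterns,
realistic inter-analyte covariance (beyond the ratios' arithmetic coupling),
missingness, or instrument drift beyond a scalar batch factor. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated generative model, not robustness to every artefact of real
acquisitions.

## Numerical and operational choices

* Problem sizes in the shipped tests: full default cohorts (46 subjects,
  ~5,350 integrated features) for the workflow experiments — 20 planted-
  subtype cohorts and several structureless ones; 50-60 seeds for
  calibration and recovery rates; 200 random fixtures (n <= 12) for the
  index oracles; permutation references use 50-100 draws.
* Determinism: every stage is a pure function of `(config, seed)`;
  `run_workflow()` takes its own seed for the permutation references; sign
  conventions fix PCA and sPLS-DA outputs; agglomeration ties resolve by the
  deterministic lowest-index convention.
* Degenerate inputs are first-class: empty spectra, all-zero variables,
  zero-variance features, strata below the minimum size, and out-of-range
  peaks all have defined error or flagging behavior (strict vs lenient
  binning).

## Known limitations

* The composition of the 24 candidate datasets, the quantitative meaning of
  "approaching" the positive control, and the space in which that control is
  evaluated are parameterized decisions, not recovered facts.
* The acceptance comparison crosses spaces (raw or PC space for the de novo
  arm, supervised score space for the control); only scale-free indices are
  compared, and the permutation guard absorbs most — not all — of the
  residual incommensurability.
* sPLS-DA selection counts follow the hard-threshold convention; coefficients
  are not numerically identical to penalized implementations away from the
  dense limit.
* The generator's analyte locations and noise scales are conventional; rate-
  style results (retention fractions, significant-feature counts) depend on
  them and should be read as calibration of the machinery, not as clinical
  estimates.
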