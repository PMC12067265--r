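---
title: "Methods: BCR diversity trajectories, spatial clonotype colocalization, and survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BCR diversity trajectories, spatial clonotype colocalization, and survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

Checkpoint blockade (anti-PD-1) helps some cancer patients dramatically and
others not at all. Because B-cell and T-cell receptors (BCR/TCR) are somatically
recombined, their sequences act as heritable clonal barcodes: counting how many
*distinct* receptor sequences infiltrate a tumor before and after therapy
measures whether treatment diversified the infiltrating lymphocyte repertoire.
This package implements, end to end, the computational chain that connects an
anti-PD-1-induced rise in unique BCR clonotypes to T cell activation and
survival:

1. **Repertoire diversity** — unique clonotype counting from AIRR-style chain
   tables, pre/post trajectory classification, V-gene usage fingerprints.
2. **Survival stratification** — Kaplan–Meier, log-rank, and two-group Cox
   estimation on the trajectory label.
3. **Cluster-blinded attribution** — which cell cluster carries a gene's
   correlation with BCR diversity.
4. **Spatial pseudoclones** — V-gene pseudoclone assignment on segmented
   spatial transcriptomics cells, T/B colocalization against a permutation
   null, and tumor/lymph-node clone sharing.
5. **Triad occurrence** — three-way cell-type colocalization.
6. **Trajectory predictor** — a small neural classifier that predicts the BCR
   trajectory from pretreatment expression, validated by arm-specific survival
   stratification.
7. **A synthetic cohort generator** that plants known effects so every stage is
   testable without patient data.

# Definitions and conventions

* A **clonotype** is keyed by `(locus, v_call, junction)` — the V gene plus the
  CDR3 nucleotide junction. This is the conventional single-chain definition
  and is robust to missing J calls. Counts are **cell-level**: after the
  dominant-chain filter each cell contributes one vote per locus.
* The **dominant-chain filter** keeps, for each `(sample, cell, locus)`, the
  record with the highest `duplicate_count`, ties broken by lexicographically
  smallest junction. This is deterministic and order-invariant, and guards
  against doublet inflation.
* **BCR counts pool IGH/IGK/IGL** keys (each key carries its locus). Spatial
  BCR tracking uses **IGH only**: in cross-modality validation only the heavy
  chain shows a matched usage pattern, so light chains carry no tracking
  signal.
* **Induced diversity** means strictly more unique clonotypes post-treatment
  than pre-treatment (`delta > 0`); a tie is not an increase. **Static
  diversity** is "high" when a count strictly exceeds the cohort median.
* **Usage correlation** between two samples is the Spearman correlation of
  V-gene frequency vectors over the union support (genes nonzero in at least
  one sample, `other` bucket excluded, minimum support 3). Spearman is robust
  to the compositional scale mismatch between probe counts and transcript
  counts.

# Survival analysis

`km_estimate()`, `logrank_test()` and `cox_two_group()` are tidy wrappers over
the `survival` package: product-limit estimation, the standard two-group
log-rank statistic with hypergeometric variance (df = 1), and maximum
partial-likelihood estimation of a single binary group effect with **Breslow
tie handling** and a Wald 95% CI on the log scale. Ties are rare at these
cohort sizes, so the simplest correct tie convention was chosen. The test suite
cross-checks all three against independent oracles written from the defining
formulas: hand product-limit arithmetic, direct hypergeometric tabulation, and
a grid search of the Breslow partial likelihood at $10^{-4}$ resolution. No
covariate adjustment is implemented (two groups only), matching the unadjusted
two-group reading of the meta-analysis estimate.

# Cluster-blinded correlation attribution

Expression is library-size normalized per cell to 10,000 counts, `log1p`
transformed, and averaged per sample (**pseudobulk**); this is the dominant
convention for 5′ scRNA-seq and is recorded in output metadata. For each gene,
`gene_diversity_correlation()` reports the Pearson correlation of pseudobulk
expression with the sample's unique BCR clonotype count, with
Benjamini–Hochberg q-values across genes; zero-variance genes are excluded
rather than assigned R = 0, and at least 4 overlapping samples are required.

`cluster_blinding_delta()` recomputes the correlation with one cluster's cells
excluded and reports `delta = |R_full| - |R_blinded|` — "correlation strength"
read as magnitude, so positive delta means the blinded cluster carried the
correlation. Blinding that empties more than half of the samples skips the
cluster with a warning. A cluster label that exists (e.g. a factor level) but
has no cells is a no-op, with delta exactly 0.

At 30 samples the sampling noise of a correlation is roughly
$(1-\rho^2)/\sqrt{27} \approx 0.17$; attribution of a planted correlation of
0.4 is therefore probabilistic per gene, and recovery rates are asserted over
replicate cohorts, not single draws.

# Spatial pseudoclones and colocalization

Spatial cells are assigned to **pseudoclones** by their maximal-count V-gene
probe (ties lexicographic, all-zero cells unassigned); B-lineage cells use IGH
probes, T-lineage cells TR probes. The proximity graph connects cells within
**20 µm** (inclusive boundary — the inclusive convention is this package's
choice for determinacy), computed exactly by blocked all-pairs distances and
verified against an $O(n^2)$ oracle.

`neighborhood_enrichment()` scores the observed count of proximal type-a/type-b
pairs against a seeded null that permutes cell-type labels over fixed
positions. `pseudoclone_colocalization()` scores every (T pseudoclone, B
pseudoclone) pair's proximal link count against a null permuting V-gene
assignments within T cells and within B cells; both report z-scores, and the
permutation default is 1,000.

A pair is flagged **colocalized** at `z >= 3` with at least 2 observed links.
Two considerations set this default above the conventional 2 SD: (i) a map
yields hundreds of simultaneous pair tests, so an uncorrected 2 SD flag admits
~2% false pairs; and (ii) those false flags are size-biased — chance links are
proportional to the product of pseudoclone sizes — which injects a negative
artifact into any downstream statistic stratified by the flag. Planted pairs in
synthetic maps score z ≥ 6, and the threshold is configurable.

`shared_pair_fraction()` takes the lymph-node pair universe (both member
pseudoclones detected with ≥ 1 cell), splits it by the colocalized flag, and
reports the fraction of pairs whose member V genes are both also detected in
the tumor, plus the colocalized/non-colocalized ratio.
`shared_vs_exclusive_expression()` compares marker expression (defaults MKI67,
CD69, ENTPD1, on `log1p` counts) between T cells of compartment-shared and
compartment-exclusive clones with a Wilcoxon rank-sum test per compartment.

# Triad occurrence

`triad_occurrence_probability()` enumerates proximal A–B pairs (unordered,
deduplicated) and reports the fraction with at least one type-C cell within the
radius of **at least one** pair member. The published metric's exact formula
lives in supplementary material not reproduced here, so this operationalization
is labeled a reconstruction; the strict variant (`mode = "both"`, C near each
member) is provided and reported alongside. One C cell may serve many pairs;
one shared radius covers pair formation and third-member proximity, separately
configurable. `triad_enrichment()` adds a label-permutation null with add-one
smoothed empirical p. The statistic is invariant to rigid motions, symmetric in
the pair types, and monotone nondecreasing in radius; all three properties are
asserted in tests along with exact agreement with an $O(n^3)$ oracle.

# The trajectory predictor

`differential_expression()` runs a per-gene Wilcoxon rank-sum test between
`increase` and `no_increase` pretreatment samples (the source analysis does not
name its test; Wilcoxon is the assumption-light default), BH q-values, and the
log2 fold change of group means (increase minus no-increase); selection
defaults to `q < 0.05` and `|log2FC| >= 1`, both configurable.

`train_predictor()` fits a single-hidden-layer feed-forward network (logistic
activations, cross-entropy loss, weight decay 0.01, width 32 — the smallest
architecture adequate for a ~117-gene input) on standardized gene inputs with a
seeded stratified 20% withheld split. Prediction is a pure function of the
stored weight vector: the forward pass is implemented in the package, so
exported JSON weight manifests (doubles stored as `%.17g` strings) reload
bit-stably. External cohorts are harmonized by per-cohort gene-wise
standardization (stated in output metadata); model genes missing from an
external matrix are imputed at the training mean up to 20%, refused beyond.
`evaluate_predictions()` stratifies survival by predicted class within each
treatment arm; the non-PD-1 control arm is the specificity check — a
checkpoint-specific signal should stratify only the PD-1 arm.

# The synthetic cohort generator

The generator emulates the study design: paired pre/post tumor samples per
patient, long clinical follow-up, a targeted spatial panel, and draining
lymph-node maps for a subset of patients. Defaults are the study conditions:

* **93 patients**, half planted with induced BCR diversification; planted
  hazard ratio **0.46** for the increased group on an exponential baseline
  (1/500 per day), right-censored at **2,564 days**. Censoring is
  noninformative at a fixed horizon — the real cohort's clinical follow-up
  scheme is not available.
* Unique clonotype counts are Poisson: pre mean 40, post mean 80 (increased)
  or 40 (flat). The post draw is **conditioned on the planted ordering**
  (strictly greater than pre for increased patients, at most pre for flat), so
  truth labels are simultaneously consistent with the generating rates and
  exactly recoverable by the strict `post > pre` rule. A rejection cap falls
  back to the boundary value for extreme user-supplied rates.
* Clone sizes follow a discrete power law $P(k) \propto k^{-2.5}$ truncated at
  50 — the standard heavy-tail assumption for repertoires; the ML exponent
  recovered from $10^5$ draws is asserted within ±0.1.
* V-gene usage is Dirichlet with symmetric concentration 0.5 (real usage
  spectra are strongly skewed; at realistic per-sample cell counts a flatter
  spectrum would leave no measurable fingerprint). IGH and TR usage are drawn
  **once per patient-timepoint** and shared across the repertoire and spatial
  modalities, so patient-and-timepoint matched samples agree; light chains are
  drawn independently per sample, so only IGH carries a matched signal.
* Expression is negative binomial (mean 0.3, dispersion 2, lognormal gene
  effects) over a **480-gene panel** with 8 clusters and 5-gene marker blocks
  (5-fold up). For the planted genes (defaults CD69, IFNG, TNF) the planted
  cluster's mean is shifted by $\exp(0.6\,\eta_{sg})$ with
  $\eta_{sg} = \rho z_s + \sqrt{1-\rho^2}\,\varepsilon_{sg}$, where $z_s$ is
  the standardized BCR count. The latent $\rho$ is calibrated up by the ~15%
  attenuation of the exponential link and count noise so the realized
  pseudobulk correlation lands near the configured target; realized values are
  recorded in `truth`. Setting `planted_corr_cluster = "all"` spreads the same
  shift over every cluster (the attribution control).
* Spatial maps place background cells by complete spatial randomness on a
  1 mm² field with compartment-specific type mixes. In treated maps, each
  planted (TR V, IGH V) pair seeds a partner activated CD8 T cell within 20 µm
  of a fraction `colocalization_rate` of its B pseudoclone members — this
  seeding is also what couples paired pseudoclone sizes. Lymph-node maps plant
  B cell/Tfh/activated-CD8 triads around a fraction `triad_rate` of B cells.
  Pair sharing into the tumor is planted at `sharing_rate_colocalized` = 0.3
  per colocalized pair versus `sharing_rate_exclusive` = 0.08 per gene
  otherwise, putting the planted sharing ratio in the middle of the 2–10×
  range. The magnitudes of all spatial effects are calibration choices — no
  quantitative effect sizes exist for them in the source analysis.
* One global seed drives a hierarchical seed tree (cohort → patient → sample),
  so subsetting patients never changes other patients' draws, and identical
  configurations are byte-identical.

```{r example}
library(clonotrackr)
cfg <- cohort_config(n_patients = 12, seed = 1)
coh <- generate_cohort(cfg, include = c("repertoire", "survival"))
traj <- diversity_trajectories(coh$clonotypes, "BCR")
survival_by_trajectory(traj, coh$survival)$cox
```

## What the generator does and does not emulate

It emulates clonotype tables, clustered counts, spatial point maps, and
survival with planted, recoverable effects. It does **not** emulate raw reads,
UMI collapsing, or receptor assembly (generation starts at clonotype calls);
segmentation errors, probe cross-hybridization, or spatial density gradients;
batch effects or cohort-specific normalization differences; informative
censoring or competing risks. Passing tests therefore demonstrate that the
statistics recover planted effects under their own model assumptions — they do
not certify performance on real data with those additional artifacts.

# Numerical choices and degenerate inputs

* Ties: dominant-chain filter (junction lexicographic), pseudoclone assignment
  (gene-name lexicographic), display-gene selection (gene-name lexicographic,
  disjoint lists).
* Undefined results are flagged, not silently zeroed: usage correlation with
  support < 3, enrichment with an absent type, triad occurrence with no
  proximal pair, size correlation with < 4 pairs or zero variance, sharing
  with no lymph-node pairs, Cox with a no-event group (monotone likelihood
  flag).
* All permutation procedures take explicit seeds; permutation p-values use
  add-one smoothing.
* Empirical z-scores use the permutation null's mean and standard deviation;
  at least 100 permutations are required, 1,000 by default.

# Problem sizes in the test suite

The packaged checks run 200 replicate 93-patient cohorts for hazard-ratio
recovery; 20 replicate 15-patient (30-sample) cohorts for attribution; 50
complete-spatial-randomness maps for null calibration; maps of 500–1,600 cells
for spatial statistics (exact-oracle checks at ≤ 500 cells); 100 three-patient
cohorts for usage validation; and a 60-sample training cohort with 50 external
120-patient cohorts for the predictor. These sizes were chosen so the full
suite runs in minutes on one core while keeping Monte-Carlo error well inside
the asserted margins.

# Known limitations

* The triad metric is a reconstruction (see above); both proximity modes are
  reported, but neither is guaranteed to match the unpublished formula.
* Whether the source counts clonotypes at cell level or UMI level is unstated;
  cell-level is implemented and flagged in output metadata.
* Pseudobulk means are one of several aggregation choices; the alternative
  (per-cell correlations) is not implemented.
* The Cox estimate is unadjusted; cancer-type stratification in a
  meta-analysis setting is out of scope.
* The colocalized flag is a per-pair threshold, not a graded "degree of
  coclustering"; the underlying z-scores are returned so users can stratify
  continuously.
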