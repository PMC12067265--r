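# clonotrackr

Tools for asking whether checkpoint blockade **diversified** the B-cell
repertoire inside a tumor — and what that diversification did. B-cell and
T-cell receptors (BCR/TCR) are somatically recombined, so each receptor
sequence is a heritable clonal barcode: counting distinct sequences in paired
pre/post anti-PD-1 tumor biopsies measures induced clonal diversity, which can
then be tied to T cell activation, spatial T/B clone interactions, and patient
survival. `clonotrackr` implements that full analysis chain as composable,
tibble-in/tibble-out functions, for computational immunologists working with
single-cell immune-receptor calls, targeted spatial transcriptomics, and
clinical outcomes.

## What it computes

* **Repertoire diversity** — unique clonotype counts per sample (key:
  locus + V gene + CDR3 nucleotide junction, cell-level after a deterministic
  dominant-chain filter), pre/post **trajectory classification**
  (induced diversity ⇔ strictly more unique clonotypes post-treatment),
  above-median static classification, and V-gene usage fingerprints with
  matched/mismatched cross-modality validation (Spearman; IGH-only for BCR).
* **Survival stratification** — Kaplan–Meier, the two-group log-rank test
  (hypergeometric variance, df = 1), and the two-group Cox model

  $$h(t \mid g) = h_0(t)\, e^{\beta g}, \qquad \widehat{HR} = e^{\hat\beta},$$

  with Breslow ties and a Wald 95% CI on $\log HR$.
* **Cluster-blinded attribution** — per-gene Pearson correlation of pseudobulk
  expression (library-size normalized, log1p) with the sample's unique BCR
  count, BH q-values, and the **blinding delta**
  $\Delta_{gc} = |R_g^{\text{full}}| - |R_g^{\text{blind }c}|$ that attributes
  each correlation to the cell cluster carrying it.
* **Spatial pseudoclones** — dominant-V-gene pseudoclone assignment on
  segmented spatial cells, a 20 µm proximity graph, permutation-null
  neighborhood enrichment, T/B pseudoclone colocalization z-scores,
  tumor/lymph-node clone-pair sharing, and shared-vs-exclusive clone
  expression comparisons.
* **Triad occurrence** — the fraction of proximal A–B cell pairs with a third
  cell type within the radius of a pair member, with a label-permutation null.
* **Trajectory predictor** — Wilcoxon + fold-change gene selection and a small
  feed-forward network that predicts the BCR trajectory from pretreatment
  expression, evaluated by arm-specific survival stratification (a non-PD-1
  control arm as the specificity check).
* **A synthetic cohort generator** (`generate_cohort()`) that emulates every
  input — AIRR-style chain tables, clustered counts, spatial maps, survival —
  with planted, recoverable ground truth and full seeded determinism.

## Worked example

Generate a 12-patient synthetic cohort with the default planted effects
(hazard ratio 0.46 for patients whose unique BCR clonotype count rises after
treatment), classify trajectories, and stratify survival:

```r
library(clonotrackr)

cfg  <- cohort_config(n_patients = 12, seed = 1)
coh  <- generate_cohort(cfg, include = c("repertoire", "survival"))
traj <- diversity_trajectories(coh$clonotypes, "BCR")
head(traj, 4)
#> # A tibble: 4 × 6
#>   patient_id receptor_class pre_count post_count delta increased
#>   <chr>      <chr>              <int>      <int> <int> <lgl>
#> 1 pt001      BCR                   49         43    -6 FALSE
#> 2 pt002      BCR                   43         71    28 TRUE
#> 3 pt003      BCR                   40         35    -5 FALSE
#> 4 pt004      BCR                   42         39    -3 FALSE

res <- survival_by_trajectory(traj, coh$survival)
res$cox
#> Cox proportional hazards (Breslow ties): increased vs flat
#>   HR = 0.324 (95% CI 0.079-1.329), p = 0.1176
res$logrank
#> Log-rank test: flat vs increased
#>   chi-square = 2.6875 (df = 1), p = 0.1011, events = 10
```

Each patient row shows the unique BCR clonotype count before and after
treatment; `increased` is the strict `post > pre` call. The Cox hazard ratio
of 0.32 estimates the planted protective effect of induced diversification
(0.46) — at 12 patients the interval is wide and the log-rank test is not yet
significant; at the full 93-patient scale the estimator concentrates around
the planted value (see the acceptance script below). `tidy()` and `glance()`
methods return these results as tibbles, and `autoplot(res$km)`,
`plot_trajectories()`, `plot_attribution()`, and `plot_volcano()` draw the
standard figures.

The methods vignette
(`vignettes/clonotype-diversity-pipeline.Rmd`) documents the models, the
generator's planted effects, parameter defaults with units, and numerical
conventions.

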