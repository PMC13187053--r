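---
title: "Stage- and region-resolved biomarker discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage- and region-resolved biomarker discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Alzheimer's disease pathology spreads through the brain in a stereotyped
sequence summarized by the Braak score (0–VI), from transentorhinal
involvement through limbic spread to neocortical degeneration. Bulk
RNA-seq of post-mortem tissue from multiple brain regions, as in the
Mount Sinai Brain Bank (MSBB) cohort, makes it possible to ask two
questions at once: *when* (at which stage) a gene's expression becomes
informative about pathology, and *where* (in which region) that signal
lives. `stagemarker` implements an explainable machine-learning pipeline
that answers both: a three-class Braak-stage classifier per region, exact
Shapley attribution of each gene's contribution per stage, and a
multi-layer validation framework that separates reproducible biomarkers
from artifacts of a single data split.

Because the motivating cohort is controlled-access, the package ships a
synthetic cohort generator that reproduces the cohort's *structure* —
stage-group sizes, region count, class imbalance, low-variance genes,
duplicate identifiers, correlated pathway blocks — with planted,
recoverable differential signals. Every downstream stage is exercised and
tested against that generator.

# The pipeline

For each brain region independently:

1. **Preprocessing.** The expression matrix is oriented samples × genes.
   Genes with raw variance strictly below 0.1 are removed. Each surviving
   gene is robust-scaled, `(x - median) / IQR` (IQR = 75th − 25th
   percentile, linear interpolation), then Z-score standardized to zero
   mean and unit SD (population convention, ddof = 0). Quality control
   records the mean of per-gene means (≈ 0) and the mean of per-gene SDs
   (≈ 1) at this point. Finally, genes sharing an ENTREZ identifier are
   aggregated by element-wise mean. QC precedes aggregation deliberately:
   averaging standardized columns changes their variances, so the
   mean-of-SDs claim holds only pre-aggregation.
2. **Label engineering.** Braak 0–II → class 0 (Early), III–IV → 1
   (Mid), V–VI → 2 (Late); samples with missing or ambiguous scores are
   dropped at alignment.
3. **Split and balancing.** A stratified 70/30 split (largest-remainder
   per-class allocation). SMOTE oversampling is applied *only* to the
   training portion: each minority class is raised to the majority count
   by interpolating between a minority sample and one of its k nearest
   same-class neighbors (k = min(5, n − 1), uniform interpolation
   weight). The test set is never touched.
4. **Model.** An XGBoost multiclass soft-probability classifier with
   n_estimators = 100, max_depth = 10, learning_rate = 0.005,
   subsample = 0.5, colsample_bytree = 0.5, reg_alpha = 0.1,
   reg_lambda = 0.5. Training is single-threaded with a fixed seed, so
   every fit is bit-reproducible.
5. **Evaluation.** Accuracy, per-class and macro F1, and one-vs-rest
   macro-averaged ROC AUC on the untouched test set. The one-vs-rest
   variant was chosen because the macro AUC's averaging scheme was
   genuinely open; one-vs-one is not currently exposed.
6. **Attribution.** Exact path-dependent tree-ensemble Shapley values
   (TreeExplainer algorithm) per sample × gene × class, on the margin
   (log-odds) scale that feeds the softmax. Local accuracy — base value
   plus attributions equals the margin — is asserted in the test suite at
   1e-4. A gene's global importance for a stage is the mean absolute
   attribution over a sample set.

## The validation framework

Three evidence layers are combined per (gene, stage, region):

* **Stability** — 5-fold stratified cross-validation re-runs the whole
  pipeline (SMOTE, training, attribution) per fold and records each
  stage's top-k genes (k = 20, matching the top-gene lists; the stability
  k is not dictated by the method and is configurable). Stability is the
  fraction of folds in which the gene appears: by construction a multiple
  of 1/K.
* **Test importance** — mean absolute attribution over the held-out test
  samples only, guarding against overfitting-driven selection.
* **Composite score** — `0.4·train + 0.3·test + 0.3·stability`, where the
  two importances are min–max normalized within their (region, stage)
  vector. The normalization method was an open choice; min–max was chosen
  because the downstream thresholds (≥ 0.8 "high importance") presuppose
  a [0, 1] scale. A constant vector maps to zeros.

Confidence tiers use stability plus the gene's position in the
(region, stage) test-importance distribution: High (stability ≥ 0.8 and
importance strictly above the 75th percentile), Medium (≥ 0.6 and above
the median), Low (≥ 0.4), otherwise Excluded. Strict inequalities for the
percentile comparisons and weak ones for stability follow the framework's
wording exactly; percentiles use linear interpolation. Class-specific
(per-stage) test importance is used rather than pooled importance — the
pooled alternative would blur exactly the stage specificity the pipeline
exists to resolve.

## Permutation significance

The observed statistic per gene is the stage-maximum mean absolute
attribution from the real fit. Stage labels are permuted B times and the
full pipeline (SMOTE, training, attribution on the same samples) is
re-run per permutation — permuting labels while refitting is the only
scheme that nulls the model-fitting process itself. P-values use the
add-one estimator `(1 + #{null ≥ obs}) / (B + 1)` so they are never zero,
and Benjamini–Hochberg step-up correction yields q-values; significance
is declared at q < 0.005. B below 19 is refused outright (p resolution).

A resolution caveat worth stating: with B = 100 the smallest attainable
p is ~0.0099, so after BH correction across thousands of genes the
q < 0.005 threshold is effectively unreachable at desk scale. Positive
significance counts at that threshold require B in the thousands. The
package's tests therefore verify the *null* behavior (no false
discoveries on cohorts with no signal; super-uniform p-values), which is
the property the permutation machinery must guarantee at any B.

## Regional aggregation

Per stage, the per-region importance vectors are assembled genes ×
regions. Rows (genes) are normalized by their maximum — the convention
is forced by published row-normalized tables whose rows contain exact 1s
— so each gene votes for its most responsive region. Column means over
all genes with nonzero importance, followed by a final min–max across
regions, give the stage's regional profile (the radar-plot values; a
constant vector degenerates to zeros with a warning). Heatmap tables keep
the overall top-k genes (summed within-region min–max-normalized
importance) with rows and columns sorted by overall importance, ties by
ID. The cross-stage overlap statistic counts genes appearing in more than
one stage's top-20 list over the total 60 selections.

## Co-expression validation

Biological sanity of a candidate biomarker is checked by Spearman
correlation against a pathway panel (GABAergic, mitochondrial,
inflammatory, synaptic, core-AD, or custom gene lists) within the region
where the biomarker matters most. Only pairs with ≥ 5 overlapping
samples are tested; two-sided p < 0.05 is significant. P-values use the
exact null distribution for n ≤ 10 without ties and the t approximation
otherwise, with average ranks under ties.

# The synthetic cohort generator

The generator emulates the study conditions rather than any real
biology:

* 33 / 40 / 51 subjects in the Early / Mid / Late groups. (The motivating
  cohort's printed group sizes sum to 124; the generator follows the
  group sizes, which are what the classifier conditions depend on.)
  Braak scores are drawn uniformly within each group's range, since only
  group membership is used downstream.
* Eleven regions (Hipp, Caud, Dors, IFG, ITG, MTG, PCC, PC, Puta, TP,
  Amyg) sharing one ENTREZ-style gene universe, 2,000 genes per region
  at desk scale (the real cohort measures ~36,000; a per-region override
  exists for emulating the amygdala's larger universe). Region
  generation is sub-seeded from the master seed, so adding a region
  never perturbs the others.
* Baseline expression is lognormal (positive, heavy-tailed,
  heterogeneous variances; meanlog ~ U(0.5, 2), sdlog ~ U(0.3, 0.8)),
  with a negative-binomial alternative for count realism. No
  distributional detail was available to match, so these were chosen
  once as a realistic bulk-expression stand-in.
* Ten planted differential genes per stage per region (disjoint across
  stages, mirroring the near-disjoint top-gene lists), shifted by
  `effect_size` standard deviations in the samples of their stage;
  the default effect is 1.5 SD, the recovery study condition.
* 10% near-constant genes (variance ≪ 0.1) exercising the variance
  filter; 5% duplicate-ID genes with distinct values exercising
  aggregation; one latent-factor pathway block per region (biomarker +
  6 panel genes at correlation 0.6) exercising co-expression recovery.

What the generator does *not* emulate: realistic gene–gene correlation
networks beyond the single pathway block, batch effects, library-size
variation, count overdispersion structure, or any real AD biology.
Passing tests therefore demonstrate that the machinery recovers planted
signals under controlled conditions — not that it would recover the
published gene lists, which require the controlled-access data.

# Numerical choices and degenerate inputs

* Variance filter: strict `<` on the threshold, population variance on
  the raw values; a gene at exactly the threshold survives. Whether the
  original filter ran on raw counts or normalized values is unknowable
  from the description; the threshold is configurable.
* Zero-IQR genes under robust scaling: mapped to all-zero columns by
  default (`"zeros"`), or dropped (`"skip_gene"`). The default lets the
  variance filter, not the scaler, decide a gene's fate.
* Z-scoring uses ddof = 0 so post-hoc SDs are exactly 1; all-zero
  columns pass through unchanged.
* Ties in top-k rankings break by ascending gene ID; ranked lists are
  fully deterministic.
* Min–max of a constant vector is defined as zeros (importance
  semantics: nothing stands out).
* Missing expression values are rejected at ingest, never imputed.
* Sub-seeds for folds, permutations, SMOTE and regions derive
  deterministically from the master seed and stay below 2^31.

# Problem sizes used in the test suite

Unit tests run on compact cohorts (40–100 genes, one or two regions)
where a model fit takes well under a second. The quantitative
end-to-end checks use: the full 124 × 2,000 region for preprocessing QC;
ten replicate 2,000-gene cohorts at effect 1.5 SD for planted-gene
recovery through the confidence framework; and five replicate 60-gene
null cohorts at B = 99 permutations (300 gene-level tests) for FDR
control. These sizes were chosen so the whole suite completes on a
single CPU in well under half an hour while keeping every statistical
property testable.

# Known limitations

* Attributions are on the margin scale; descriptions of contributions
  "to the predicted probability" are interpreted as the margin feeding
  the softmax.
* Heatmap and confidence importances default to training-set
  attributions (test-set importance enters through the confidence
  framework); which set feeds published heatmaps is not specified, so
  this is configurable at the function level.
* The q < 0.005 permutation threshold is effectively unreachable at
  desk-scale B (see above); published positive counts at that threshold
  imply a much larger, unprinted B.
* Radar "surface area" comparisons between stages are not implemented;
  the per-region profile values are the deliverable.
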