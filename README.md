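# stagemarker

Stage- and region-resolved transcriptomic biomarker discovery for
Alzheimer's disease progression.

## What it does, and for whom

Braak staging describes the stereotyped spread of neurofibrillary-tangle
pathology through the brain (stages 0–VI, grouped here as Early 0–II,
Mid III–IV, Late V–VI). Given per-region bulk RNA-seq expression
matrices and clinical metadata — as in multi-region post-mortem cohorts
like the Mount Sinai Brain Bank — `stagemarker` asks which genes carry
stage information and in which brain regions, and how much of that
signal survives rigorous validation. It is aimed at computational
biologists analyzing staged neurodegeneration cohorts, and at
methodologists who need a fully reproducible, testable reference
implementation of SHAP-validated biomarker discovery.

The pipeline, per region:

1. preprocessing: low-variance filter (variance < 0.1 removed), per-gene
   robust scaling by IQR, Z-score standardization, duplicate-ENTREZ
   aggregation by mean, with QC metrics;
2. three-class staging: stratified 70/30 split, SMOTE balancing of the
   training data only, an XGBoost `multi:softprob` classifier
   (100 trees, depth 10, η = 0.005, subsample/colsample 0.5, L1 = 0.1,
   L2 = 0.5), evaluated by accuracy, per-class/macro F1 and macro
   one-vs-rest ROC AUC;
3. attribution: exact TreeExplainer Shapley values φ<sub>g,i</sub><sup>(s)</sup>
   per sample i, gene g, stage s, with gene-level importance
   I<sub>g,s</sub> = mean<sub>i</sub>|φ<sub>g,i</sub><sup>(s)</sup>|;
4. validation, per (gene, stage, region):
   * stability = (#folds where g is in the stage's top-k) / K over
     K = 5 stratified CV re-runs of the whole pipeline,
   * test importance = mean |SHAP| on the untouched test set,
   * composite score = 0.4·Ĩ<sub>train</sub> + 0.3·Ĩ<sub>test</sub> +
     0.3·stability (Ĩ: min–max normalized within region × stage),
   * confidence tiers High / Medium / Low / Excluded from stability and
     test-importance percentiles,
   * permutation significance: stage labels permuted B times with full
     pipeline re-runs, p = (1 + #{null ≥ obs})/(B + 1),
     Benjamini–Hochberg FDR;
5. aggregation across regions: per-stage heatmap tables, row-normalized
   regional importance profiles (radar values), cross-stage top-20
   overlap, and Spearman co-expression of biomarkers against pathway
   panels (≥ 5 overlapping samples, p < 0.05).

A synthetic multi-region cohort generator (`generate_cohort()`,
`null_cohort()`) reproduces the structure of the motivating cohort —
33/40/51 subjects per stage group, 11 regions, class imbalance,
low-variance genes, duplicate IDs, correlated pathway blocks, planted
stage-specific effects — so the entire pipeline runs and is tested
without any controlled-access download.

## Worked example

```r
library(stagemarker)

cfg <- synthetic_config(regions = c("Hipp", "PCC", "MTG"), n_genes = 300,
                        n_planted = 8, effect_size = 2, seed = 101)
cohort <- generate_cohort(cfg)
report <- run_full_pipeline(cohort, hp = stage_hyperparams(n_estimators = 50),
                            seed = 101)
report$performance
#> # A tibble: 3 × 8
#>   region accuracy auc_macro f1_class0 f1_class1 f1_class2 f1_macro missing_classes
#>   <chr>     <dbl>     <dbl>     <dbl>     <dbl>     <dbl>    <dbl> <chr>
#> 1 Hipp          1         1         1         1         1        1 ""
#> 2 PCC           1         1         1         1         1        1 ""
#> 3 MTG           1         1         1         1         1        1 ""
```

With a planted 2-SD effect the classifier separates the three stage
groups perfectly in all regions — far above the 33.3% random baseline
for a three-class problem. The validation framework then ranks genes:

```r
head(dplyr::arrange(report$confidence, dplyr::desc(validation_score)), 3)
#> # A tibble: 3 × 12
#>   region gene   stage train_importance_raw test_importance_raw train_norm test_norm stability ...
#> 1 Hipp   287663 Early               0.0671              0.0641          1         1         1
#> 2 Hipp   914803 Mid                 0.0705              0.0718          1         1         1
#> 3 Hipp   288430 Late                0.0528              0.0555          1         1         1
```

These top genes are planted ground-truth genes: maximal normalized train
and test importance, present in the stage's top-20 in all five CV folds
(stability 1), hence validation score 1 and High confidence. The
cross-stage overlap of the top-20 lists is small
(`report$overlap$overlap_fraction` = 0.05), mirroring the
stage-specificity of the planted signals, and the planted pathway blocks
are recovered by co-expression:

```r
report$coexpression
#> # A tibble: 3 × 8
#>   gene   region pathway         n_tested n_significant mean_abs_rho max_rho min_rho
#> 1 732226 Hipp   synthetic_block        6             6        0.628   0.693   0.498
#> 2 754891 MTG    synthetic_block        6             6        0.558   0.590   0.506
#> 3 787028 PCC    synthetic_block        6             6        0.566   0.621   0.497
```

Each block's biomarker correlates significantly with all six of its
panel genes (target latent correlation 0.6). `emit_reports(report, dir)`
writes every table to CSV/JSON; `plot_importance_heatmap()`,
`plot_region_profile()`, `plot_confidence_tiers()` and
`autoplot(report$performance)` draw the standard figures.

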