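# mrscore

Identify gut-microbiome features associated with non-alcoholic fatty liver
disease (NAFLD) from tabular cohort data, and summarise them as a
per-individual **Microbiome Risk Score (MRS)** built from Shapley
attributions of a tree-ensemble classifier. The package is aimed at
microbiome epidemiologists who have an individuals × taxa relative-abundance
table, clinical/dietary metadata, a binary outcome, and (optionally) a
faecal-metabolite intensity matrix — and who want the full
classify → explain → score → associate → metabolome workflow as tested,
reproducible R functions rather than a one-off notebook.

## The method

1. **Bench.** Four probabilistic classifier families — gradient-boosted
   trees (xgboost), random forest (ranger), RBF support-vector machine
   (e1071) and ridge logistic regression (glmnet) — are trained on the same
   stratified 80/20 split with cross-validated tuning, and compared by
   held-out ROC/AUC.
2. **Explain.** The boosted-tree model is decomposed per individual with
   **exact interventional Shapley values**: for feature *j* of individual
   *i*, φᵢⱼ satisfies local accuracy φ₀ + Σⱼ φᵢⱼ = f(xᵢ) to machine
   precision. The implementation enumerates tree leaves per background row
   (no sampling for tree models) and is validated against a 2ᵖ brute-force
   coalition oracle.
3. **Score.** The top-20 features by mean |φ| are selected; among them the
   taxa become the score components, and

   MRSᵢ = Σⱼ s(i,j),  s(i,j) = 1 if φᵢⱼ > 0, else 0,

   an integer in [0, k] counting the taxa that push individual *i* towards
   disease. Individuals are stratified by the cohort median (scores at the
   median go to the low group) and into quartiles Q1–Q4 (Q1 = reference).
4. **Associate.** Logistic regression estimates odds ratios with Wald 95%
   CIs for the MRS per unit, per quartile, and per SD of each component
   taxon, under four nested adjustment sets (crude; +age, sex; +marital
   status, education, income, smoking, alcohol, tea, energy intake; +BMI).
5. **Metabolome.** Significantly different metabolites (SDMs) between
   high/low-MRS or case/control strata must pass all of: Student's t on
   log intensities p < 0.05, Benjamini–Hochberg q < 0.1, and fold change
   > 2 or < 0.5. Bray–Curtis ordination and Spearman correlations link
   metabolites to the score.

A synthetic-cohort simulator with planted ground truth (causal taxa with
known per-SD log-odds effects, metabolites with known fold changes,
prevalence calibrated to 56.1%) makes every step testable; see the methods
vignette (`vignettes/mrscore-methods.Rmd`) for the generative model and all
numerical conventions.

## Worked example

```r
library(mrscore)
library(dplyr)

cfg    <- sim_config(n_individuals = 600, seed = 42)
cohort <- simulate_cohort(cfg)
split  <- split_cohort(cohort, ratio = 0.8, seed = 42)
model  <- train_classifier(split$train, "gbt", cv_folds = 5, tune = FALSE,
                           seed = 42)
evaluate_roc_auc(model, split$test)
#> <mrs_roc> AUC = 0.716 ( 71 cases / 49 controls )

shap <- shap_attribute(model, cohort, seed = 42)
sel  <- select_top_k(rank_importance(shap), k = 20,
                     taxa = taxa_names(cohort))
mrs  <- compute_mrs(shap, sel$taxa) |> median_split() |> quartile_bins()
glance(mrs)
#> # A tibble: 1 × 6
#>       n     k  mean median   min   max
#>   <int> <int> <dbl>  <dbl> <int> <int>
#> 1   600    19  9.46     10     2    15

joined <- left_join(cohort, mrs, by = "id")
fit_logistic_or(joined, "mrs", adjustment = "model3")
#> # A tibble: 1 × 8
#>   exposure level model     or ci_low ci_high  p_value     n
#>   <chr>    <chr> <chr>  <dbl>  <dbl>   <dbl>    <dbl> <int>
#> 1 mrs      <NA>  model3  2.29   2.00    2.62 4.85e-34   600
```

The held-out AUC of 0.716 says the boosted trees discriminate cases from
controls well above chance at this reduced cohort size; 19 of the top 20
features are taxa, so the score has k = 19 components and each individual
carries between 2 and 15 risk-direction taxa. The adjusted odds ratio of
2.29 (95% CI 2.00–2.62) per unit of MRS means each additional
positively-attributed taxon roughly doubles the odds of NAFLD in this
synthetic cohort, where 12 causal taxa were in fact planted.

The metabolite screen recovers the simulator's planted fold changes:

```r
mets <- simulate_metabolites(cohort, cfg)
sdm  <- sdm_screen(mets, case = cohort$nafld == 1)
filter(sdm, sdm)
#> # A tibble: 4 × 10
#>   metabolite mean_case mean_control fold_change log2_fc statistic   p_value
#>   <chr>          <dbl>        <dbl>       <dbl>   <dbl>     <dbl>     <dbl>
#> 1 met_007        1159.        480.         2.41    1.27      27.0 1.84e-105
#> 2 met_052        1489.        583.         2.55    1.35      23.9 3.07e- 89
#> 3 met_120         230.         80.7        2.85    1.51      22.0 3.04e- 79
#> 4 met_185         657.        273.         2.41    1.27      14.8 2.44e- 42
```

exactly the four metabolites planted at fold change 2.5 (empirical log2 FC
1.27–1.51 against the planted log2(2.5) ≈ 1.32), and nothing else.

`run_pipeline(pipeline_config(), "out/", seed = 1)` chains all stages and
writes one TSV per result plus a JSON manifest; rerunning with the same
config and seed reproduces every table byte for byte. A shell wrapper
lives at `inst/scripts/run_pipeline.R`.

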