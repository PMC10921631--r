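---
title: "Methods: microbiome risk scores from Shapley attributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microbiome risk scores from Shapley attributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cross-sectional cohort studies of non-alcoholic fatty liver disease (NAFLD)
increasingly pair 16S gut-microbiome profiles with clinical, dietary and
lifestyle metadata. A recurring analysis pattern is: train a flexible
classifier of disease status on all features, explain it with per-individual
Shapley attributions, keep the most important taxa, and collapse their
attribution *signs* into a single integer per person — a Microbiome Risk
Score (MRS) — that is then carried into ordinary epidemiological models
(logistic odds ratios under nested adjustment sets) and linked to faecal
metabolites. `mrscore` implements that pattern as a tested, reproducible
pipeline, and ships a synthetic-cohort generator with planted ground truth so
every step can be validated against known answers.

## The generative model behind the simulator

`sim_config()` / `simulate_cohort()` emulate the *structure* of a discovery
cohort of 1546 individuals: 23 named covariates (age, sex, marital status,
education, income, BMI, waist, hip, fasting glucose, TC, LDL, TG, HDL,
smoking, tea, alcohol, physical activity, and five dietary intakes) drawn
with moments typical of a middle-aged community cohort, plus 249 taxa
relative abundances and a binary outcome with 56.1% prevalence.

Taxa are generated as log-normal intensities with a rank-decreasing location
(`mu` from 2.5 down to −3.5 on the natural-log scale) and per-taxon scale
drawn from U(0.6, 1.6), hit by structural zeros with probability 0.3 (the
ten most abundant taxa are exempt so no row can collapse), then closed to
the unit simplex. A log-normal-to-simplex construction was chosen over a
Dirichlet because planted effects stay interpretable on the log-abundance
scale and the marginals are heavy-tailed like real 16S relative abundances.

The outcome is Bernoulli with log-odds linear in covariate z-scores and in
z-scores of `log10(abundance + 1e-6)`:

- **Causal taxa.** Twelve taxa (indices 3–120, spread across the abundance
  ranks) carry per-SD log-odds effects of magnitude 0.40–0.60, eight
  risk-increasing and four protective. These are deliberately stronger than
  the per-SD odds ratios typically reported for single taxa in real cohorts
  (≈ 1.3 and below): the simulator's job is to provide *recoverable* ground
  truth for testing selection and scoring, and effects near the real-data
  scale would make recovery a coin flip at n = 1546. The mixed signs keep
  the score construction honest — the MRS counts positive *attributions*,
  which must line up with risk regardless of whether high abundance is
  harmful or protective.
- **Covariates.** Adiposity, lipid and glycaemic covariates dominate
  (BMI 0.45, waist 0.25, TG 0.30, glucose 0.20, HDL −0.20 per SD, plus
  smaller sex/age/energy terms), mirroring the known risk-factor profile of
  fatty liver disease. Together with the taxa this puts the Bayes-optimal
  AUC in the mid-0.8s, the regime reported for boosted-tree classifiers on
  such cohorts.
- **Intercept calibration.** When `prevalence_target` is set the intercept
  is solved by `uniroot` on the mean predicted probability (monotone in the
  intercept, so the root is unique); the draw then hits the target up to
  binomial noise. Calibration fails loudly when `n * target < 1`.

`simulate_metabolites()` adds 198 strictly positive log-normal metabolite
intensities in 15 subclasses. Planted metabolites (default: four at fold
change 2.5) have `log(fold change)` added to their case-stratum logs, so the
case/control *geometric-mean* ratio equals the configured fold exactly in
expectation; all other metabolites are null. Because within-group log-scale
variances are equal by construction, the arithmetic-mean fold change used by
the screen has the same expectation.

What the simulator does **not** emulate: covariate–covariate and
taxon–taxon correlation (features are independent given the outcome model),
longitudinal sampling, batch effects, sequencing depth variation, and
compositional bias from closure interacting with planted effects. Passing
tests therefore demonstrate correctness of the machinery under a known
model, not performance guarantees on real data.

## Classifier bench

`split_cohort()` partitions 80/20, stratified by class with per-class
rounding, so the train fraction of cases is preserved to within one
individual. `train_classifier()` fits one of four probabilistic families on
the covariate + taxa feature matrix:

| family | engine | tuned over | probability |
|---|---|---|---|
| `gbt` | xgboost, logistic objective | depth 1/2/4 at eta 0.05; rounds by CV early stopping (patience 100, cap 5000) | `plogis(margin)` |
| `rf` | ranger, 500 trees | `mtry` by OOB Brier | averaged leaf frequency |
| `svm` | e1071 RBF | cost × gamma by CV accuracy | own Platt scaling |
| `logistic` | glmnet ridge | lambda by `cv.glmnet` | `plogis(link)` |

Design notes. The 5000-round figure is read as a *cap* with early stopping
on cross-validated log loss — boosting that long without stopping would
badly overfit at this n. The boosted trees use row subsampling 0.8 and
per-tree feature subsampling 0.3: with ~250 of 272 features carrying no
signal, column subsampling is what lets weak true effects into the trees;
shallow depths suit a near-additive risk surface and were selected by CV
loss. SVM probabilities come from the package's own Platt scaling (a
logistic fit of the labels on the decision values) rather than libsvm's
internal probability training, whose un-seedable C `rand()` state would
break the pipeline's byte-identical re-run guarantee. For random forests
the "margin" is the predicted probability itself — attributions for that
family are on the probability scale.

`evaluate_roc_auc()` builds the empirical ROC with tied scores grouped
(diagonal segments) and integrates by trapezoid, which is provably the
midrank Mann–Whitney concordance estimate; the suite verifies that identity
on random instances and against an independent ROC implementation.

## Exact interventional Shapley attributions

`shap_attribute()` explains individual predictions on the margin scale. For
tree ensembles it computes **exact interventional Shapley values**: the
value function is

\[ v(S) = \frac{1}{|B|}\sum_{r \in B} f(r \text{ with features } S \text{ set from } x), \]

with background \(B\) a seeded 256-row subsample of the training set. The
algorithm walks each tree once per background row: a node whose feature is
still unconstrained and routes \(x\) and \(r\) to different children splits
the path into an "from-x" branch and a "from-r" branch; at a leaf reached
with \(a\) from-x features \(A\) and \(b\) from-r features \(D\), the leaf
value \(w\) contributes \( w\,(a-1)!\,b!/(a+b)! \) to every \(\phi_j, j \in A\)
and \(-w\,a!\,(b-1)!/(a+b)!\) to every \(j \in D\) — the closed-form Shapley
value of the induced unanimity-style game. Summing over leaves, trees and
background rows gives attributions that are exact (no sampling), satisfy
local accuracy to double precision
(\(\phi_0 + \sum_j \phi_{ij} = f(x_i)\)), and give exactly zero to features
the forest never splits on. A \(2^p\) coalition-enumeration oracle
(`shapley_bruteforce()`) validates the fast path on random forests with
p ≤ 8.

Choices worth recording:

- **Margin scale, not probability.** Attributions live in log-odds units
  for boosted trees, where additivity across trees is exact and local
  accuracy holds to machine precision. Only signs feed the risk score, and
  `plogis` is monotone, so the score is unaffected by this choice; plots
  label the units explicitly.
- **Interventional, not path-dependent.** The tree-path/cover variant
  answers a conditional-expectation question that depends on the training
  covariance; the interventional variant is the one with a clean
  brute-force definition, so it is the one an enumeration oracle can
  certify. Background choice is config-exposed (`background`,
  `n_background`).
- **Linear closed form.** The ridge-logistic family gets
  \(\phi_j = \beta_j (x_j - \bar r_j)\) exactly; non-tree, non-linear
  families (SVM) fall back to seeded Monte-Carlo permutation sampling, whose
  efficiency error is Monte-Carlo-sized rather than zero, and which cycles
  the background deterministically so whole-number background passes make
  efficiency exact.
- **Zeros are meaningful.** Attributions are never rounded; a taxon with
  attribution exactly 0 contributes 0 to the score by the strict `> 0`
  rule below.

`rank_importance()` orders features by mean |attribution| (ties broken
alphabetically, for determinism); `select_top_k()` keeps the top 20 by
default and reports the taxa among them — the score's component list.
`dependence_table()` sorts one feature's attributions by feature value and
reports the first sign change of a lowess smooth as the risk threshold, or
`NA` when no stable crossing exists; constant features are flagged
degenerate.

## The Microbiome Risk Score

For selected taxa \(j = 1..k\),

\[ MRS_i = \sum_{j=1}^{k} s_{ij}, \qquad
   s_{ij} = \begin{cases} 1 & \text{if } shap_{ij} > 0 \\
                          0 & \text{if } shap_{ij} \le 0. \end{cases} \]

The score is an integer in \([0, k]\), invariant to any strictly positive
rescaling of the attributions, and satisfies the complement identity
\(MRS(\text{shap}) = k - MRS(-\text{shap})\) whenever no attribution is
exactly zero. `median_split()` assigns scores strictly above the cohort
median to the high-risk group — scores *at* the median go low, so a median
of 5 yields the "MRS > 5 vs MRS ≤ 5" partition. `quartile_bins()` cuts at
the interpolated 25/50/75 percentiles with boundary ties assigned to the
lower quartile (a deterministic convention; any other tie rule would make
quartile membership depend on sort order). For validation cohorts the
intended usage is to apply the *discovery-trained* model to the new
cohort's features and recompute attributions — the model transports, the
attributions are recomputed.

## Association models

`fit_logistic_or()` is maximum-likelihood logistic regression with Wald 95%
intervals on the exposure coefficient, exponentiated. The four adjustment
sets are nested: crude; + age, sex; + marital status, education, income,
smoking, alcohol, tea, energy intake; + BMI. Categorical covariates are
dummy-coded against their first level; incomplete cases are dropped with a
message; collinear terms are dropped with a warning; |log OR| > 20 is
treated as separation and refused rather than reported. Per-SD taxa
exposures standardise by the *discovery* cohort's mean and SD
(`per_sd_standardize()` takes an explicit reference so validation cohorts
reuse the discovery scale). Quartile models use Q1 as the reference with
its OR pinned at 1 by construction.

## Metabolite screen

`sdm_screen()` flags significantly different metabolites between two strata
(high/low score, or case/control) when **all three** strict criteria hold:
equal-variance two-sample Student's t on `log(x + 1)` with p < 0.05,
Benjamini–Hochberg q < 0.1 across the 198 tests, and raw-scale
arithmetic-mean fold change > 2 or < 0.5 (equivalently |log2 FC| > 1 — the
flag and the log2 threshold are exactly consistent). A fold change of
exactly 2 is *not* flagged. Welch's t is available behind a flag.
Fold changes use raw-scale means, not back-transformed log means; the
pseudocount is 1.0 on the intensity scale. FDR is computed within each
comparison (score strata and outcome strata separately), since the two
screens ask different questions. `bh_fdr()` delegates to
`stats::p.adjust(method = "BH")`; the test suite certifies it against a
quadratic step-up implementation written from the definition.

"PCA on Bray–Curtis" is internally contradictory (PCA is Euclidean), so
`ordinate()` offers both readings: `"pca"` is an eigendecomposition of
autoscaled log intensities, `"pcoa_braycurtis"` (the default in the
pipeline) is classical metric scaling of the Bray–Curtis dissimilarity on
raw intensities. Both report per-axis variance fractions. Spearman
correlations use midranks with a two-sided t-approximation p-value and
refuse constant input.

## Reproducibility and problem sizes

`run_pipeline()` derives one seed per stage from the master seed through a
single documented `sample.int` draw, runs every stage in order, and writes
each table with a manifest digest comment header; re-running with the same
config and seed reproduces every table byte for byte (base-R readers are
used on the way in because their `strtod` parsing is exactly
round-trip-stable, which the fast vroom parser is not). All thresholds
(k = 20, split 0.8, 10 folds, 5000-round cap, p 0.05 / q 0.1 / FC 2) are
config keys defaulting to the values above.

The test suite exercises the full default cohort (n = 1546, 272 features)
across five simulation seeds for selection recovery, association strength
and bench sanity; coverage of the Wald interval is checked over 500
simulated cohorts of n = 1000; the null false-flag rate of the metabolite
screen over 100 seeds of 198 null metabolites; and end-to-end determinism
on a reduced cohort (n = 400, four families, 3 folds), since bytewise
equality is size-invariant. `scripts/acceptance.R` re-runs the full
default pipeline once (5 CV folds) and reports every headline quantity it
computes.

## Known limitations

- Attribution exactness is specific to additive tree ensembles expressed in
  the internal forest format (xgboost and ranger converters are provided);
  SVM explanations are Monte-Carlo estimates.
- The simulator's independence assumptions understate the collinearity of
  real metadata; selection stability on real cohorts will be worse than on
  synthetic ones.
- The per-SD taxa ORs model `log10(abundance + 1e-6)`; for taxa with many
  structural zeros the pseudocount dominates the low tail and the OR mixes
  presence/absence with abundance effects — as it does in the field's
  standard practice.
- Weighted or continuous (raw attribution sum) scores are deliberately not
  implemented; the integer count is the construct under study.
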