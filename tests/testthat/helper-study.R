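# Full-size study runs shared between the recovery, association, local
# accuracy and bench checks (computed once per seed, cached for the session).
study_cache <- new.env(parent = emptyenv())

study_run <- function(seed) {
  key <- paste0("run", seed)
  if (!exists(key, envir = study_cache)) {
    cohort <- simulate_cohort(sim_config(seed = seed))
    split <- split_cohort(cohort, ratio = 0.8, seed = seed)
    model <- train_classifier(split$train, "gbt", cv_folds = 5,
                              max_boost_rounds = 2000, tune = FALSE,
                              seed = seed)
    auc <- evaluate_roc_auc(model, split$test)$auc
    shap <- shap_attribute(model, cohort, n_background = 256, seed = seed)
    sel <- select_top_k(rank_importance(shap), k = 20,
                        taxa = taxa_names(cohort))
    causal <- sprintf("taxon_%03d", cohort_truth(cohort)$causal_taxa)
    mrs <- quartile_bins(median_split(compute_mrs(shap, sel$taxa)))
    joined <- dplyr::left_join(cohort, mrs, by = "id")
    assign(key, list(
      cohort = cohort, model = model, auc = auc, shap = shap,
      selection = sel, recovered = length(intersect(sel$taxa, causal)),
      mrs = mrs, joined = joined), envir = study_cache)
  }
  get(key, envir = study_cache)
}
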