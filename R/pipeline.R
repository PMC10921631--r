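#' Pipeline configuration
#'
#' Bundles the simulator settings with every analysis threshold: split
#' ratio 0.8, 10 cross-validation folds, a 5000-round boosting cap, top-20
#' feature selection, SDM screening at p < 0.05, FDR q < 0.1 and fold
#' change > 2 (all defaults, all overridable).
#'
#' @param sim A [sim_config()].
#' @param families Classifier families for the bench stage.
#' @param ratio Train fraction of the stratified split.
#' @param cv_folds Cross-validation folds for tuning.
#' @param max_boost_rounds Boosting-round cap.
#' @param tune Tune over the documented hyperparameter grids.
#' @param top_k Number of features selected from the importance ranking.
#' @param n_background Background subsample size for attributions.
#' @param p_threshold,fdr_threshold,fc_threshold SDM screening thresholds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            families = c("gbt", "rf", "svm", "logistic"),
                            ratio = 0.8, cv_folds = 10,
                            max_boost_rounds = 5000, tune = TRUE,
                            top_k = 20, n_background = 256,
                            p_threshold = 0.05, fdr_threshold = 0.1,
                            fc_threshold = 2) {
  structure(list(sim = sim, families = families, ratio = ratio,
                 cv_folds = cv_folds, max_boost_rounds = max_boost_rounds,
                 tune = tune, top_k = top_k, n_background = n_background,
                 p_threshold = p_threshold, fdr_threshold = fdr_threshold,
                 fc_threshold = fc_threshold),
            class = "pipeline_config")
}

# Accepts a pipeline_config, a plain list, or a YAML file path. Missing keys
# are reported exhaustively in one message.
as_pipeline_config <- function(config) {
  if (inherits(config, "pipeline_config")) return(config)
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a pipeline_config, list or YAML path")
  required <- setdiff(names(formals(pipeline_config)), "sim")
  missing_keys <- setdiff(c("sim", required),
                          names(config)[!vapply(config, is.null, TRUE)])
  # every key has a default; only flag keys explicitly set to NULL
  if (length(missing_keys) > 0 && any(missing_keys %in% names(config))) {
    abort(paste0("config keys set to NULL: ",
                 paste(intersect(missing_keys, names(config)),
                       collapse = ", ")))
  }
  sim <- config$sim
  if (!inherits(sim, "sim_config")) {
    if (is.null(sim)) sim <- list()
    if (!is.null(sim$planted_sdm)) {
      sim$planted_sdm <- as.data.frame(dplyr::bind_rows(sim$planted_sdm))
    }
    sim <- do.call(sim_config, sim)
  }
  args <- config[intersect(names(config), required)]
  do.call(pipeline_config, c(list(sim = sim), args))
}

stage_seeds <- function(master, n = 8) {
  # documented splitter: one R sample.int draw under the master seed
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

config_digest <- function(config, seed) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(c(deparse(unclass(config)), as.character(seed)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order — simulate the cohort and metabolites,
#' benchmark the classifier families on a shared stratified split, compute
#' exact attributions for the boosted-tree model on the whole cohort, select
#' the top-k features and their taxa subset, build the Microbiome Risk Score
#' with median and quartile strata, fit the per-unit / per-SD / quartile
#' logistic association models under all four adjustment sets, screen the
#' metabolites for significant differences by risk-score stratum and by
#' outcome, correlate metabolites with the score, and ordinate samples by
#' Bray-Curtis — writing one TSV per result plus a JSON run manifest. Every
#' source of randomness is derived from the single `seed` through a
#' documented splitter, so re-running with the same config and seed
#' reproduces byte-identical tables. Any stage failure aborts with an error
#' naming the stage.
#'
#' @param config A [pipeline_config()], a plain list of its keys, or a YAML
#'   file path.
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list of class `mrs_pipeline` with the in-memory
#'   stage results, the output paths and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1L,
                         verbose = TRUE) {
  config <- as_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stage_seeds(seed)
  digest <- config_digest(config, seed)
  timings <- list()
  say <- function(...) if (verbose) message("[mrscore] ", ...)
  stage <- function(name, expr) {
    say("stage ", name)
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      abort(paste0("stage ", name, " failed: ", conditionMessage(e)))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  cohort <- stage("simulate", simulate_cohort(config$sim, seed = seeds[1]))
  mets <- stage("metabolites",
                simulate_metabolites(cohort, config$sim, seed = seeds[2]))
  bench <- stage("bench",
                 compare_models(cohort, families = config$families,
                                ratio = config$ratio,
                                cv_folds = config$cv_folds,
                                max_boost_rounds = config$max_boost_rounds,
                                tune = config$tune, seed = seeds[3]))
  explain_family <- if ("gbt" %in% names(bench$models)) "gbt" else
    bench$results$family[1]
  model <- bench$models[[explain_family]]
  shap <- stage("attribute",
                shap_attribute(model, cohort,
                               n_background = config$n_background,
                               seed = seeds[4]))
  sel <- stage("select", {
    ranking <- rank_importance(shap)
    select_top_k(ranking, k = config$top_k,
                 taxa = taxa_names(cohort))
  })
  ranking <- rank_importance(shap)
  mrs <- stage("score", {
    if (length(sel$taxa) == 0) abort("no taxa among the selected features")
    compute_mrs(shap, sel$taxa) %>% median_split() %>% quartile_bins()
  })
  assoc <- stage("associate", {
    joined <- left_join(cohort, mrs, by = "id")
    per_unit <- purrr::map_dfr(paste0("model", 1:4), function(mod) {
      fit_logistic_or(joined, "mrs", adjustment = mod)
    })
    quart <- purrr::map_dfr(paste0("model", 1:4), function(mod) {
      quartile_association(joined, adjustment = mod)
    })
    per_sd <- purrr::map_dfr(sel$taxa, function(tx) {
      d <- mutate(joined,
                  .z = per_sd_standardize(log10(.data[[tx]] + 1e-6)))
      fit_logistic_or(d, ".z", adjustment = "model3") %>%
        mutate(exposure = tx)
    })
    bind_rows(mutate(per_unit, analysis = "mrs_per_unit"),
              mutate(quart, analysis = "mrs_quartile"),
              mutate(per_sd, analysis = "taxa_per_sd"))
  })
  metab <- stage("metabolomics", {
    sdm_mrs <- sdm_screen(mets, case = mrs$risk_group == "high",
                          p_threshold = config$p_threshold,
                          q_threshold = config$fdr_threshold,
                          fc_threshold = config$fc_threshold)
    sdm_outcome <- sdm_screen(mets, case = cohort$nafld == 1,
                              p_threshold = config$p_threshold,
                              q_threshold = config$fdr_threshold,
                              fc_threshold = config$fc_threshold)
    corr <- correlate_metabolites(mets, mrs$mrs, target_name = "mrs")
    ord <- ordinate(mets, method = "pcoa_braycurtis")
    list(sdm_mrs = sdm_mrs, sdm_outcome = sdm_outcome, corr = corr,
         ord = ord)
  })

  paths <- stage("write", {
    write_cohort(cohort, out_dir, digest = digest)
    write_metabolites(mets, file.path(out_dir, "metabolites.tsv"),
                      digest = digest)
    tabs <- list(
      bench_report.tsv = bench$results,
      importance.tsv = ranking,
      selected_features.tsv = tibble(
        feature = sel$features,
        is_taxon = sel$features %in% taxa_names(cohort)),
      mrs.tsv = mrs,
      associations.tsv = assoc,
      sdm_mrs.tsv = metab$sdm_mrs,
      sdm_outcome.tsv = metab$sdm_outcome,
      metabolite_correlations.tsv = metab$corr,
      ordination.tsv = metab$ord$scores)
    for (nm in names(tabs)) {
      write_tsv_commented(tabs[[nm]], file.path(out_dir, nm), digest)
    }
    file.path(out_dir, c("metadata.tsv", "taxa.tsv", "metabolites.tsv",
                         names(tabs)))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("mrscore")),
    master_seed = seed, stage_seeds = seeds, manifest_digest = digest,
    config = unclass_deep(config),
    explained_family = explain_family,
    mrs_components = attr(mrs, "component_taxa"),
    file_md5 = as.list(tools::md5sum(paths)),
    stage_seconds = timings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", out_dir)
  invisible(structure(
    list(cohort = cohort, metabolites = mets, bench = bench, shap = shap,
         ranking = ranking, selection = sel, mrs = mrs,
         associations = assoc, metabolomics = metab,
         manifest = manifest, out_dir = out_dir),
    class = "mrs_pipeline"))
}

unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  if (is.data.frame(x)) return(as.list(x))
  x
}

#' @export
print.mrs_pipeline <- function(x, ...) {
  cat("<mrs_pipeline> outputs in", x$out_dir, "\n")
  cat("  best family:", x$bench$results$family[1],
      sprintf("(AUC %.3f)", x$bench$results$auc[1]), "\n")
  cat("  MRS components:", length(attr(x$mrs, "component_taxa")),
      "taxa | SDMs by MRS:", sum(x$metabolomics$sdm_mrs$sdm),
      "| SDMs by outcome:", sum(x$metabolomics$sdm_outcome$sdm), "\n")
  invisible(x)
}
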