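#' Configuration for the synthetic-cohort simulator
#'
#' Bundles every knob of the generative model: cohort size, the covariate and
#' taxa blocks, the planted (ground-truth) effects on the binary fatty-liver
#' outcome, and the metabolite block with its planted fold changes. Defaults
#' emulate the structure of a discovery cohort of 1546 individuals carrying
#' 23 clinical/dietary covariates and 249 taxa relative abundances with a
#' 56.1% outcome prevalence, and a 198-metabolite matrix in 15 subclasses.
#'
#' @param n_individuals Cohort size.
#' @param n_taxa Number of taxa columns.
#' @param n_covariates Number of covariate columns. The first 23 follow the
#'   named clinical/dietary variables (age, sex, BMI, ...) with realistic
#'   moments; any extras are standard-normal filler covariates.
#' @param causal_taxa Integer indices of taxa with planted outcome effects.
#' @param taxa_effects Signed per-SD log-odds effect for each causal taxon
#'   (applied to the z-score of log10 relative abundance).
#' @param covariate_effects Named per-SD log-odds effects for covariates.
#' @param intercept Log-odds intercept, used only when `prevalence_target`
#'   is `NULL`.
#' @param prevalence_target Outcome prevalence to calibrate the intercept to
#'   (by monotone root finding); `NULL` disables calibration.
#' @param sparsity Probability of a structural zero per taxon observation
#'   (the ten most abundant taxa are never zeroed).
#' @param taxa_sigma_range Range of per-taxon log-intensity SDs.
#' @param metabolite_count,metabolite_subclasses Metabolite block dimensions.
#' @param planted_sdm Data frame with columns `metabolite` (index) and
#'   `fold_change` (>0): metabolites whose case-group geometric mean is
#'   shifted by the given fold change.
#' @param metabolite_sigma_range Range of per-metabolite log-intensity SDs.
#' @param seed Integer seed fixing all randomness of the generators.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 1546,
                       n_taxa = 249,
                       n_covariates = 23,
                       causal_taxa = c(3L, 8L, 14L, 21L, 30L, 41L, 54L, 69L,
                                       83L, 95L, 108L, 120L),
                       taxa_effects = c(0.60, 0.55, 0.50, 0.50, 0.45, 0.45,
                                        0.40, 0.40, -0.60, -0.50, -0.45, -0.40),
                       covariate_effects = c(BMI = 0.45, waist = 0.25,
                                             TG = 0.30, glucose = 0.20,
                                             HDL = -0.20, sex = 0.25,
                                             age = 0.10, energy_intake = 0.10),
                       intercept = 0,
                       prevalence_target = 0.561,
                       sparsity = 0.3,
                       taxa_sigma_range = c(0.6, 1.6),
                       metabolite_count = 198,
                       metabolite_subclasses = 15,
                       planted_sdm = data.frame(
                         metabolite = c(7L, 52L, 120L, 185L),
                         fold_change = 2.5),
                       metabolite_sigma_range = c(0.4, 0.9),
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals), n_taxa = as.integer(n_taxa),
    n_covariates = as.integer(n_covariates),
    causal_taxa = as.integer(causal_taxa), taxa_effects = taxa_effects,
    covariate_effects = covariate_effects, intercept = intercept,
    prevalence_target = prevalence_target, sparsity = sparsity,
    taxa_sigma_range = taxa_sigma_range,
    metabolite_count = as.integer(metabolite_count),
    metabolite_subclasses = as.integer(metabolite_subclasses),
    planted_sdm = planted_sdm,
    metabolite_sigma_range = metabolite_sigma_range,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_individuals <= 0 || n_taxa <= 0 || n_covariates <= 0 ||
        metabolite_count <= 0 || metabolite_subclasses <= 0) {
      abort("all counts in sim_config must be positive")
    }
    if (length(causal_taxa) != length(taxa_effects)) {
      abort("causal_taxa and taxa_effects must have equal length")
    }
    if (length(causal_taxa) > n_taxa || any(causal_taxa < 1) ||
        any(causal_taxa > n_taxa)) {
      abort("causal_taxa indices must lie in 1..n_taxa")
    }
    if (any(!is.finite(taxa_effects)) ||
        any(!is.finite(covariate_effects)) || !is.finite(intercept)) {
      abort("effects and intercept must be finite")
    }
    if (!is.null(prevalence_target)) {
      if (prevalence_target <= 0 || prevalence_target >= 1) {
        abort("prevalence_target must lie strictly between 0 and 1")
      }
      if (n_individuals * prevalence_target < 1 ||
          n_individuals * (1 - prevalence_target) < 1) {
        abort(paste0("n_individuals = ", n_individuals, " is too small to ",
                     "calibrate prevalence ", prevalence_target))
      }
    }
    if (nrow(planted_sdm) > 0) {
      if (any(planted_sdm$fold_change <= 0)) abort("fold changes must be > 0")
      if (any(planted_sdm$metabolite < 1 |
              planted_sdm$metabolite > metabolite_count)) {
        abort("planted_sdm metabolite indices must lie in 1..metabolite_count")
      }
    }
    if (sparsity < 0 || sparsity >= 1) abort("sparsity must be in [0, 1)")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> n =", x$n_individuals, "|", x$n_covariates, "covariates +",
      x$n_taxa, "taxa |", length(x$causal_taxa), "causal taxa |",
      x$metabolite_count, "metabolites | seed", x$seed, "\n")
  invisible(x)
}

# Named clinical/dietary covariates with moments typical of a middle-aged
# Chinese community cohort. Binary variables are 0/1; education and income
# are small ordinal codes treated as categorical by the association module.
sim_covariates <- function(n) {
  trunc_norm <- function(n, mean, sd, lo) pmax(rnorm(n, mean, sd), lo)
  tibble(
    age = trunc_norm(n, 64.9, 5.9, 40),
    sex = rbinom(n, 1, 0.316),
    marital_status = rbinom(n, 1, 0.142),
    education = sample(1:3, n, replace = TRUE, prob = c(0.271, 0.457, 0.272)),
    income = sample(1:4, n, replace = TRUE,
                    prob = c(0.209, 0.486, 0.045, 0.260)),
    BMI = trunc_norm(n, 23.5, 3.1, 14),
    waist = trunc_norm(n, 84.8, 8.9, 50),
    hip = trunc_norm(n, 91.5, 12.1, 55),
    glucose = trunc_norm(n, 5.5, 1.3, 2.5),
    TC = trunc_norm(n, 5.5, 1.1, 1.5),
    LDL = trunc_norm(n, 3.6, 1.0, 0.3),
    TG = rlnorm(n, meanlog = 0.2765, sdlog = 0.6221),
    HDL = trunc_norm(n, 1.6, 1.1, 0.2),
    smoking = rbinom(n, 1, 0.071),
    tea = rbinom(n, 1, 0.539),
    alcohol = rbinom(n, 1, 0.071),
    physical_activity = trunc_norm(n, 18.9, 6.9, 0),
    energy_intake = trunc_norm(n, 1719.3, 581.2, 300),
    vegetable_intake = trunc_norm(n, 332.5, 166.7, 0),
    fish_intake = trunc_norm(n, 41.4, 42.2, 0),
    red_meat_intake = trunc_norm(n, 80.3, 52.7, 0),
    fruit_intake = trunc_norm(n, 152.7, 105.1, 0),
    yogurt_intake = trunc_norm(n, 30.5, 46.2, 0))
}

#' Simulate a cohort with planted microbiome effects
#'
#' Draws a cohort table emulating a cross-sectional fatty-liver study:
#' clinical/dietary covariates with realistic moments, a heavy-tailed
#' compositional taxa block (log-normal intensities with structural zeros,
#' closed to row sum 1), and a Bernoulli outcome whose log-odds are linear in
#' covariate z-scores and in z-scores of log10 taxa relative abundance
#' (pseudocount 1e-6). When `prevalence_target` is set, the intercept is
#' solved by monotone root finding so the expected prevalence matches it.
#' The planted truth (effects, causal indices, intercept, standardisation
#' constants) is stored in `attr(, "truth")`.
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A tibble of class `mrs_cohort`: `id`, covariate columns, taxa
#'   columns (`taxon_001`, ...; each row of taxa sums to 1), and the binary
#'   outcome column `nafld`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  validate_sim_config(config)
  set.seed(seed %||% config$seed)
  n <- config$n_individuals
  Tn <- config$n_taxa

  cov_tbl <- sim_covariates(n)
  if (config$n_covariates < ncol(cov_tbl)) {
    cov_tbl <- cov_tbl[, seq_len(config$n_covariates)]
  } else if (config$n_covariates > ncol(cov_tbl)) {
    extra <- config$n_covariates - ncol(cov_tbl)
    filler <- as_tibble(setNames(
      as.data.frame(matrix(rnorm(n * extra), n, extra)),
      sprintf("cov_%02d", ncol(cov_tbl) + seq_len(extra))))
    cov_tbl <- dplyr::bind_cols(cov_tbl, filler)
  }

  # heavy-tailed compositional taxa: log-normal intensities, rank-decreasing
  # location, structural zeros, then closure to the simplex
  taxa_names <- sprintf("taxon_%03d", seq_len(Tn))
  mu <- seq(2.5, -3.5, length.out = Tn)
  sigma <- runif(Tn, config$taxa_sigma_range[1], config$taxa_sigma_range[2])
  intensity <- exp(sweep(matrix(rnorm(n * Tn), n, Tn), 2, sigma, `*`) +
                     matrix(mu, n, Tn, byrow = TRUE))
  pi0 <- rep(config$sparsity, Tn)
  pi0[seq_len(min(10, Tn))] <- 0
  zero <- matrix(runif(n * Tn) < matrix(pi0, n, Tn, byrow = TRUE), n, Tn)
  intensity[zero] <- 0
  rel <- intensity / rowSums(intensity)
  colnames(rel) <- taxa_names

  # outcome model: logistic in covariate z-scores and log10-abundance z-scores
  zscale <- function(m) {
    mu <- colMeans(m); s <- apply(m, 2, sd)
    s[s == 0] <- 1
    list(z = sweep(sweep(m, 2, mu), 2, s, `/`), mean = mu, sd = s)
  }
  covm <- as.matrix(cov_tbl)
  covz <- zscale(covm)
  beta <- setNames(numeric(ncol(covm)), colnames(covm))
  keep <- intersect(names(config$covariate_effects), names(beta))
  beta[keep] <- config$covariate_effects[keep]
  log_rel <- log10(rel + 1e-6)
  taxz <- zscale(log_rel)
  gamma <- setNames(numeric(Tn), taxa_names)
  gamma[config$causal_taxa] <- config$taxa_effects
  lp <- drop(covz$z %*% beta + taxz$z %*% gamma)

  if (!is.null(config$prevalence_target)) {
    icept <- uniroot(function(c) mean(plogis(c + lp)) -
                       config$prevalence_target,
                     interval = c(-30, 30), tol = 1e-10)$root
  } else {
    icept <- config$intercept
  }
  outcome <- rbinom(n, 1, plogis(icept + lp))

  cohort <- dplyr::bind_cols(
    tibble(id = sprintf("S%05d", seq_len(n))), cov_tbl, as_tibble(rel),
    tibble(nafld = outcome))
  attr(cohort, "covariate_names") <- colnames(covm)
  attr(cohort, "taxa_names") <- taxa_names
  attr(cohort, "truth") <- list(
    causal_taxa = config$causal_taxa, taxa_effects = gamma[config$causal_taxa],
    covariate_effects = beta[beta != 0], intercept = icept,
    linear_predictor = lp,
    taxa_log10_mean = taxz$mean, taxa_log10_sd = taxz$sd)
  class(cohort) <- c("mrs_cohort", class(cohort))
  cohort
}

#' Simulate a faecal-metabolite intensity matrix for a cohort
#'
#' Strictly positive log-normal intensities for `metabolite_count`
#' metabolites grouped into subclasses. Metabolites listed in
#' `config$planted_sdm` have their log-intensity shifted by `log(fold_change)`
#' in the case stratum (`nafld == 1`), so the case/control geometric-mean
#' ratio equals the configured fold change; all other metabolites are null.
#'
#' @param cohort A cohort from [simulate_cohort()] (needs `id` and `nafld`).
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed + 1` when given.
#' @return A tibble (class `mrs_metabolites`): `id` plus one positive column
#'   per metabolite, with `attr(, "subclasses")` and `attr(, "planted")`.
#' @export
simulate_metabolites <- function(cohort, config = sim_config(), seed = NULL) {
  validate_sim_config(config)
  if (!all(c("id", "nafld") %in% names(cohort))) {
    abort("cohort must contain id and nafld columns")
  }
  set.seed(seed %||% (config$seed + 1L))
  n <- nrow(cohort)
  m <- config$metabolite_count
  met_names <- sprintf("met_%03d", seq_len(m))
  subclass_pool <- c("amino_acids", "bile_acids", "benzoic_acids",
                     "carbohydrates", "cholines", "fatty_acids", "indoles",
                     "nucleotides", "organic_acids", "peptides", "phenols",
                     "phenylpropanoids", "short_chain_fatty_acids",
                     "sphingolipids", "vitamins")
  subclasses <- setNames(
    rep_len(rep(subclass_pool, length.out = config$metabolite_subclasses), m)[
      order(rep_len(seq_len(config$metabolite_subclasses), m))],
    met_names)
  mu <- runif(m, 2, 8)
  sigma <- runif(m, config$metabolite_sigma_range[1],
                 config$metabolite_sigma_range[2])
  logx <- sweep(matrix(rnorm(n * m), n, m), 2, sigma, `*`) +
    matrix(mu, n, m, byrow = TRUE)
  if (nrow(config$planted_sdm) > 0) {
    case <- cohort$nafld == 1
    for (r in seq_len(nrow(config$planted_sdm))) {
      j <- config$planted_sdm$metabolite[r]
      logx[case, j] <- logx[case, j] + log(config$planted_sdm$fold_change[r])
    }
  }
  x <- exp(logx)
  colnames(x) <- met_names
  out <- dplyr::bind_cols(tibble(id = cohort$id), as_tibble(x))
  attr(out, "subclasses") <- subclasses
  attr(out, "planted") <- config$planted_sdm
  class(out) <- c("mrs_metabolites", class(out))
  out
}

## -- cohort accessors ------------------------------------------------------

#' Cohort column roles
#'
#' `taxa_names()` and `covariate_names()` recover the taxa and covariate
#' column sets of a cohort table (from attributes when present, otherwise by
#' the `taxon_` naming convention); `cohort_truth()` returns the planted
#' simulation ground truth, or `NULL` for real data; `feature_matrix()`
#' returns the numeric classifier input (covariates + taxa, in that order).
#'
#' @param cohort A cohort tibble.
#' @return Character vectors, a list, or a numeric matrix respectively.
#' @export
taxa_names <- function(cohort) {
  attr(cohort, "taxa_names") %||%
    grep("^taxon_", names(cohort), value = TRUE)
}

#' @rdname taxa_names
#' @export
covariate_names <- function(cohort) {
  attr(cohort, "covariate_names") %||%
    setdiff(names(cohort), c("id", "nafld", taxa_names(cohort)))
}

#' @rdname taxa_names
#' @export
cohort_truth <- function(cohort) attr(cohort, "truth")

#' @rdname taxa_names
#' @export
feature_matrix <- function(cohort) {
  cols <- c(covariate_names(cohort), taxa_names(cohort))
  m <- as.matrix(as.data.frame(cohort)[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- cohort$id
  m
}

# Structural checks shared by the simulator and the readers.
validate_cohort <- function(cohort, tol = 1e-6) {
  if (anyDuplicated(cohort$id)) {
    abort(paste0("duplicated id: ",
                 cohort$id[duplicated(cohort$id)][1]))
  }
  if (!all(cohort$nafld %in% c(0, 1)) || anyNA(cohort$nafld)) {
    abort("outcome column nafld must be 0/1 with no missing values")
  }
  tx <- taxa_names(cohort)
  tm <- as.matrix(as.data.frame(cohort)[, tx, drop = FALSE])
  if (any(!is.finite(tm)) || any(tm < 0)) {
    bad <- which(!is.finite(tm) | tm < 0, arr.ind = TRUE)[1, ]
    abort(paste0("taxa abundance must be finite and >= 0 (first offence: row ",
                 bad[1], ", column ", tx[bad[2]], ")"))
  }
  rs <- rowSums(tm)
  off <- which(abs(rs - 1) > tol)
  if (length(off) > 0) {
    abort(paste0("taxa row ", off[1], " (id ", cohort$id[off[1]],
                 ") sums to ", format(rs[off[1]]), ", not 1"))
  }
  invisible(cohort)
}
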