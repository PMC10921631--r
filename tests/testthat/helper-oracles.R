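# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# Midrank Mann-Whitney AUC: concordant pairs + half the ties.
auc_mann_whitney <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# O(m^2) Benjamini-Hochberg step-up from the definition:
# q_i = min over j with p_(j) >= p_i of m * p_(j) / rank(j), capped at 1.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(seq_len(m), function(j) {
      if (p[ord[j]] >= p[i]) m * p[ord[j]] / j else Inf
    }, 1)
    q[i] <- min(1, min(cand))
  }
  q
}

# Count-strictly-positive MRS oracle.
mrs_count_oracle <- function(values) {
  apply(values, 1, function(row) sum(row > 0))
}

# Random complete binary tree ensemble in the internal forest format.
random_forest_fixture <- function(p, n_trees = 3, depth = 3, seed = 1) {
  set.seed(seed)
  trees <- lapply(seq_len(n_trees), function(t) {
    n_internal <- 2^depth - 1
    n_nodes <- 2^(depth + 1) - 1
    leaf <- seq_len(n_nodes) > n_internal
    data.frame(
      feature = ifelse(leaf, NA_integer_, sample(p, n_nodes, replace = TRUE)),
      split = ifelse(leaf, NA_real_, rnorm(n_nodes)),
      yes = ifelse(leaf, NA_integer_, 2 * seq_len(n_nodes)),
      no = ifelse(leaf, NA_integer_, 2 * seq_len(n_nodes) + 1),
      value = ifelse(leaf, rnorm(n_nodes), NA_real_))
  })
  shap_forest(trees, paste0("f", seq_len(p)), leq = FALSE)
}

# Tiny two-covariate cohort for classifier toys; outcome separable when
# sep = TRUE. Taxa block is a two-part composition so nothing is constant.
make_toy_cohort <- function(n = 200, sep = TRUE, seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  u <- runif(n, 0.2, 0.8)
  y <- if (sep) as.integer(x1 + x2 > 0) else rbinom(n, 1, 0.5)
  co <- tibble::tibble(id = sprintf("T%04d", seq_len(n)),
                       x1 = x1, x2 = x2,
                       taxon_001 = u, taxon_002 = 1 - u,
                       nafld = y)
  attr(co, "covariate_names") <- c("x1", "x2")
  attr(co, "taxa_names") <- c("taxon_001", "taxon_002")
  class(co) <- c("mrs_cohort", class(co))
  co
}

# Reduced simulator settings for fast unit tests.
small_sim_config <- function(n = 300, seed = 1, ...) {
  sim_config(n_individuals = n, n_taxa = 30,
             causal_taxa = c(3L, 5L, 9L, 12L),
             taxa_effects = c(0.8, 0.7, -0.8, -0.6),
             metabolite_count = 40, metabolite_subclasses = 5,
             planted_sdm = data.frame(metabolite = c(4L, 11L),
                                      fold_change = c(2.5, 0.4)),
             seed = seed, ...)
}
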