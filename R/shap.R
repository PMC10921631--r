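#' Per-individual Shapley attributions for a trained classifier
#'
#' Decomposes each individual's prediction margin into one additive
#' contribution per feature (Shapley values of the interventional game
#' \eqn{v(S) = E_r[f(r \text{ with } S \text{ set to } x)]} over a background
#' sample). Tree ensembles (`gbt`, `rf`) are handled by an exact
#' per-background-row leaf-enumeration algorithm; the ridge-logistic family
#' has the exact closed form \eqn{\phi_j = \beta_j (x_j - \bar r_j)}; other
#' families fall back to seeded Monte-Carlo permutation sampling. In every
#' case attributions satisfy local accuracy: `base_value + rowSums(values)`
#' equals the model margin (exactly for tree/linear, within Monte-Carlo error
#' for permutation sampling).
#'
#' @param model An `mrs_classifier`.
#' @param newdata Cohort tibble or feature matrix to explain.
#' @param background Background feature matrix; defaults to a seeded
#'   `n_background`-row subsample of the training set.
#' @param n_background Background subsample size (default 256).
#' @param method `"auto"` (exact tree / exact linear / permutation by
#'   family), or force `"tree"`, `"linear"`, `"permutation"`.
#' @param n_perm Number of permutations for the Monte-Carlo method.
#' @param seed Seed for the background subsample and permutation draws.
#' @return An object of class `mrs_shap`: `values` (cases x features matrix,
#'   margin units), `base_value`, `features`, `ids`, `method`.
#' @export
shap_attribute <- function(model, newdata, background = NULL,
                           n_background = 256,
                           method = c("auto", "tree", "linear", "permutation"),
                           n_perm = 64, seed = 1L) {
  method <- match.arg(method)
  X <- classifier_features(model, newdata)
  if (is.null(background)) {
    if (is.null(model$X_train)) {
      abort("no background supplied and the model carries no training sample")
    }
    background <- model$X_train
  } else if (!is.matrix(background)) {
    background <- classifier_features(model, background)
  }
  background <- background[, model$features, drop = FALSE]
  if (nrow(background) > n_background) {
    set.seed(seed)
    background <- background[sample(nrow(background), n_background), ,
                             drop = FALSE]
  }
  if (method == "auto") {
    method <- switch(model$family, gbt = "tree", rf = "tree",
                     logistic = "linear", "permutation")
  }
  values <- switch(method,
                   tree = shap_tree(model, X, background),
                   linear = shap_linear(model, X, background),
                   permutation = shap_permutation(model, X, background,
                                                  n_perm, seed))
  base <- mean(predict(model, background, type = "margin"))
  dimnames(values) <- list(rownames(X), model$features)
  structure(list(values = values, base_value = base,
                 features = model$features,
                 ids = rownames(X) %||% as.character(seq_len(nrow(X))),
                 method = method),
            class = "mrs_shap")
}

shap_tree <- function(model, X, background) {
  forest <- model$forest %||% as_shap_forest(model$fit)
  treeshap_interventional_cpp(X, background, forest$feature, forest$split,
                              forest$yes, forest$no, forest$value,
                              forest$roots, forest$leq)
}

shap_linear <- function(model, X, background) {
  beta <- drop(coef(model$fit, s = "lambda.min"))[-1]
  sweep(X, 2, colMeans(background)) %*% diag(beta, ncol(X))
}

shap_permutation <- function(model, X, background, n_perm, seed) {
  f <- function(m) predict(model, m, type = "margin")
  n <- nrow(X); p <- ncol(X)
  phi <- matrix(0, n, p)
  set.seed(seed)
  for (k in seq_len(n_perm)) {
    perm <- sample(p)
    b <- background[((k - 1) %% nrow(background)) + 1, ]
    Z <- matrix(b, n, p, byrow = TRUE, dimnames = dimnames(X))
    prev <- f(Z)
    for (j in perm) {
      Z[, j] <- X[, j]
      cur <- f(Z)
      phi[, j] <- phi[, j] + (cur - prev)
      prev <- cur
    }
  }
  phi / n_perm
}

#' @export
print.mrs_shap <- function(x, ...) {
  cat("<mrs_shap> ", nrow(x$values), " individuals x ", ncol(x$values),
      " features (", x$method, "), base value ", signif(x$base_value, 4),
      "\n", sep = "")
  invisible(x)
}

#' Rank features by mean absolute attribution
#'
#' @param shap An `mrs_shap`.
#' @return A tibble of class `mrs_importance` with `feature`, `importance`
#'   (mean |attribution| over individuals) and `rank`, in descending
#'   importance; ties are broken by feature name.
#' @export
rank_importance <- function(shap) {
  if (length(shap$values) == 0) abort("empty attribution matrix")
  out <- tibble(feature = colnames(shap$values),
                importance = unname(colMeans(abs(shap$values)))) %>%
    arrange(desc(.data$importance), .data$feature) %>%
    mutate(rank = row_number())
  class(out) <- c("mrs_importance", class(out))
  out
}

#' Select the top-k features and the taxa among them
#'
#' Mirrors the feature-selection step of the risk-score construction: the
#' `k` most important features overall are retained, and the taxa subset
#' among them becomes the component list of the Microbiome Risk Score.
#'
#' @param ranking An importance ranking from [rank_importance()].
#' @param k Number of features to keep (`1 <= k <= p`).
#' @param taxa Character vector of taxa feature names; defaults to the
#'   `taxon_` naming convention.
#' @return A list with `features` (length `k`, importance order) and `taxa`
#'   (the selected taxa, importance order).
#' @export
select_top_k <- function(ranking, k = 20,
                         taxa = grep("^taxon_", ranking$feature, value = TRUE)) {
  if (k <= 0) abort("k must be positive")
  if (k > nrow(ranking)) abort("k exceeds the number of ranked features")
  top <- ranking$feature[seq_len(k)]
  list(features = top, taxa = intersect(top, taxa))
}

#' Attribution-versus-value dependence profile for one feature
#'
#' Pairs each individual's feature value with its attribution, sorted by
#' value, and estimates the zero-crossing threshold: the smallest feature
#' value at which the lowess-smoothed attribution changes sign (the point
#' where the feature flips from protective to risk-increasing, or back).
#'
#' @param shap An `mrs_shap`.
#' @param X Cohort tibble or feature matrix the attributions were computed on.
#' @param feature Feature name.
#' @param smooth_f lowess smoother span.
#' @return A tibble with `value`, `attribution`, `smoothed`, carrying
#'   attributes `zero_crossing` (numeric or `NA`) and `degenerate` (`TRUE`
#'   for a constant feature).
#' @export
dependence_table <- function(shap, X, feature, smooth_f = 0.3) {
  if (!feature %in% colnames(shap$values)) {
    abort(paste0("unknown feature: ", feature))
  }
  Xm <- if (is.matrix(X)) X else
    as.matrix(as.data.frame(X)[, shap$features, drop = FALSE])
  v <- Xm[, feature]
  a <- shap$values[, feature]
  ord <- order(v)
  out <- tibble(value = v[ord], attribution = a[ord])
  degenerate <- length(unique(out$value)) < 2
  if (degenerate) {
    warn(paste0("feature ", feature, " is constant; dependence is degenerate"))
    out$smoothed <- out$attribution
    crossing <- NA_real_
  } else {
    out$smoothed <- lowess(out$value, out$attribution, f = smooth_f)$y
    sgn <- sign(out$smoothed)
    nz <- which(sgn != 0)
    crossing <- NA_real_
    if (length(nz) > 1) {
      flip <- which(diff(sgn[nz]) != 0)
      if (length(flip) > 0) {
        i <- nz[flip[1]]; j <- nz[flip[1] + 1]
        crossing <- mean(out$value[c(i, j)])
      }
    }
  }
  attr(out, "zero_crossing") <- crossing
  attr(out, "degenerate") <- degenerate
  out
}
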