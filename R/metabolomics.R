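#' Log-transform and autoscale a metabolite matrix
#'
#' Applies `y = log(x + pseudocount)` to every intensity. With
#' `autoscale = TRUE` each metabolite column is additionally centred and
#' scaled to unit variance — the normalisation used for ordination only;
#' fold changes are always computed on the raw intensity scale.
#'
#' @param metabolites A tibble from [simulate_metabolites()] /
#'   [read_metabolites()] (`id` + intensity columns), or a numeric matrix.
#' @param pseudocount Added before the log (default 1).
#' @param autoscale Centre/scale columns after the log transform.
#' @return A numeric matrix (samples x metabolites) with sample ids as row
#'   names.
#' @export
log_normalize <- function(metabolites, pseudocount = 1, autoscale = FALSE) {
  m <- metabolite_matrix(metabolites)
  if (any(m < 0)) abort("metabolite intensities must be non-negative")
  y <- log(m + pseudocount)
  if (autoscale) y <- scale(y)[, , drop = FALSE]
  y
}

metabolite_matrix <- function(metabolites) {
  if (is.matrix(metabolites)) {
    storage.mode(metabolites) <- "double"
    return(metabolites)
  }
  df <- as.data.frame(metabolites)
  ids <- df$id
  m <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Ordinate samples by PCA or Bray-Curtis PCoA
#'
#' `"pca"` is an eigendecomposition of the covariance of log-transformed,
#' autoscaled intensities (`prcomp`). `"pcoa_braycurtis"` is classical
#' metric scaling (`cmdscale`) of the Bray-Curtis dissimilarity computed on
#' raw intensities (`vegan::vegdist`). Both report the fraction of variance
#' (or of positive eigenvalue mass) carried by each returned axis.
#'
#' @param metabolites Metabolite tibble or matrix (samples x metabolites).
#' @param method `"pca"` or `"pcoa_braycurtis"`.
#' @param k Number of axes to return (default 2).
#' @param pseudocount Pseudocount for the PCA log transform.
#' @return An object of class `mrs_ordination`: `scores` (tibble `id`,
#'   `axis1`, `axis2`, ...), `var_explained`, `method`.
#' @export
ordinate <- function(metabolites, method = c("pca", "pcoa_braycurtis"),
                     k = 2, pseudocount = 1) {
  method <- match.arg(method)
  m <- metabolite_matrix(metabolites)
  if (nrow(m) < 3) abort("ordination needs at least 3 samples")
  if (method == "pca") {
    y <- log_normalize(m, pseudocount = pseudocount, autoscale = TRUE)
    y <- y[, apply(y, 2, function(col) all(is.finite(col))), drop = FALSE]
    pc <- prcomp(y, center = FALSE, scale. = FALSE)
    ev <- pc$sdev^2
    k_eff <- min(k, sum(ev > 1e-12))
    if (k_eff < k) warn("rank-deficient matrix; returning fewer axes")
    scores <- pc$x[, seq_len(k_eff), drop = FALSE]
    var_expl <- ev[seq_len(k_eff)] / sum(ev)
  } else {
    d <- vegan::vegdist(m, method = "bray")
    cs <- cmdscale(d, k = min(k, nrow(m) - 1), eig = TRUE)
    ev <- cs$eig[cs$eig > 1e-12]
    k_eff <- min(k, ncol(cs$points))
    if (k_eff < k) warn("degenerate dissimilarity; returning fewer axes")
    scores <- cs$points[, seq_len(k_eff), drop = FALSE]
    var_expl <- cs$eig[seq_len(k_eff)] / sum(ev)
  }
  colnames(scores) <- paste0("axis", seq_len(ncol(scores)))
  out <- list(
    scores = dplyr::bind_cols(
      tibble(id = rownames(m) %||% as.character(seq_len(nrow(m)))),
      as_tibble(scores)),
    var_explained = unname(var_expl),
    method = method)
  class(out) <- "mrs_ordination"
  out
}

#' @export
print.mrs_ordination <- function(x, ...) {
  cat("<mrs_ordination> ", x$method, ": ",
      paste0(sprintf("axis%d %.1f%%", seq_along(x$var_explained),
                     100 * x$var_explained), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Step-up FDR adjustment
#' \eqn{q_{(i)} = \min_{j \ge i} m\, p_{(j)} / j} capped at 1, returned in
#' the original order (delegates to `stats::p.adjust(method = "BH")`).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1] with no missing values")
  }
  p.adjust(p_values, method = "BH")
}

#' Screen for significantly different metabolites (SDMs)
#'
#' Per metabolite: equal-variance two-sample Student's t-test on
#' log-transformed intensities, Benjamini-Hochberg q-values across all
#' metabolites, and the raw-scale fold change (case-group mean over
#' control-group mean). A metabolite is flagged as an SDM when all three
#' strict criteria hold: `p < 0.05`, `q < 0.1`, and `FC > 2` or `FC < 0.5`
#' (equivalently `|log2 FC| > 1`).
#'
#' @param metabolites Metabolite tibble or matrix (samples x metabolites).
#' @param case Logical or 0/1 vector marking the case (exposed / high-score)
#'   group, aligned with the rows.
#' @param pseudocount Pseudocount for the log transform used by the t-test.
#' @param p_threshold,q_threshold,fc_threshold Screening thresholds
#'   (defaults 0.05, 0.1, 2; the lower fold bound is `1/fc_threshold`).
#' @param welch Use Welch's unequal-variance t-test instead of Student's.
#' @return A tibble of class `mrs_sdm`: `metabolite`, `mean_case`,
#'   `mean_control`, `fold_change`, `log2_fc`, `statistic`, `p_value`,
#'   `q_value`, `sdm` (logical flag).
#' @export
sdm_screen <- function(metabolites, case, pseudocount = 1,
                       p_threshold = 0.05, q_threshold = 0.1,
                       fc_threshold = 2, welch = FALSE) {
  m <- metabolite_matrix(metabolites)
  case <- as.logical(case)
  if (length(case) != nrow(m)) abort("case must have one entry per sample")
  if (!any(case) || !any(!case)) abort("both groups must be non-empty")
  if (sum(case) < 2 || sum(!case) < 2) {
    abort("each group needs at least 2 samples for a t-test")
  }
  y <- log(m + pseudocount)
  res <- purrr::map_dfr(seq_len(ncol(m)), function(j) {
    mc <- mean(m[case, j]); mk <- mean(m[!case, j])
    tt <- tryCatch(
      t.test(y[case, j], y[!case, j], var.equal = !welch),
      error = function(e) NULL)
    if (is.null(tt)) {
      warn(paste0("metabolite ", colnames(m)[j],
                  " skipped (degenerate t-test)"))
      return(tibble(metabolite = colnames(m)[j], mean_case = mc,
                    mean_control = mk, fold_change = mc / mk,
                    log2_fc = log2(mc / mk), statistic = NA_real_,
                    p_value = NA_real_))
    }
    tibble(metabolite = colnames(m)[j], mean_case = mc, mean_control = mk,
           fold_change = mc / mk, log2_fc = log2(mc / mk),
           statistic = unname(tt$statistic), p_value = tt$p.value)
  })
  ok <- !is.na(res$p_value)
  res$q_value <- NA_real_
  res$q_value[ok] <- bh_fdr(res$p_value[ok])
  res$sdm <- ok & res$p_value < p_threshold & res$q_value < q_threshold &
    (res$fold_change > fc_threshold | res$fold_change < 1 / fc_threshold)
  sub <- attr(metabolites, "subclasses")
  if (!is.null(sub)) res$subclass <- unname(sub[res$metabolite])
  class(res) <- c("mrs_sdm", class(res))
  res
}

#' Spearman correlation with midranks and t-approximation p-value
#'
#' Midrank (tie-corrected) Spearman rho between a metabolite and a target
#' (risk score or taxon abundance), with a two-sided p-value from the
#' t approximation \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}}.
#'
#' @param x,y Paired numeric vectors, `n >= 4`, no missing values.
#' @return A tibble with `rho`, `p_value`, `n`.
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    abort("x and y must be finite with no missing values")
  }
  n <- length(x)
  if (n < 4) abort("need at least 4 pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("constant input; Spearman correlation undefined")
  }
  rho <- cor(rank(x), rank(y), method = "pearson")
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  tibble(rho = rho, p_value = p, n = n)
}

#' Correlate every metabolite with a target variable
#'
#' Convenience wrapper applying [spearman_assoc()] across the columns of a
#' metabolite table, with Benjamini-Hochberg q-values.
#'
#' @param metabolites Metabolite tibble or matrix.
#' @param target Numeric vector (e.g. the MRS, or one taxon's abundance)
#'   aligned with the rows.
#' @param target_name Label stored in the output.
#' @return A tibble with `metabolite`, `target`, `rho`, `p_value`,
#'   `q_value`, `n`.
#' @export
correlate_metabolites <- function(metabolites, target,
                                  target_name = "target") {
  m <- metabolite_matrix(metabolites)
  if (length(target) != nrow(m)) {
    abort("target must have one entry per sample")
  }
  res <- purrr::map_dfr(seq_len(ncol(m)), function(j) {
    r <- spearman_assoc(m[, j], target)
    tibble(metabolite = colnames(m)[j], target = target_name,
           rho = r$rho, p_value = r$p_value, n = r$n)
  })
  res$q_value <- bh_fdr(res$p_value)
  res
}
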