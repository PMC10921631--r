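#' Microbiome Risk Score from binarised attributions
#'
#' For each individual, counts the selected taxa whose Shapley attribution is
#' strictly positive:
#' \deqn{MRS_i = \sum_j s_{ij}, \quad s_{ij} = 1 \text{ if } shap_{ij} > 0,
#'   \; 0 \text{ if } shap_{ij} \le 0.}
#' A zero attribution therefore contributes 0. The score is an integer in
#' `[0, k]` for `k` component taxa and depends only on attribution signs, so
#' it is invariant to any strictly positive rescaling of the attributions.
#'
#' @param shap An `mrs_shap` (attributions of the discovery-trained model;
#'   for a validation cohort, apply that same model to the new features).
#' @param selected_taxa Character vector of component taxa (from
#'   [select_top_k()]).
#' @return A tibble of class `mrs_score`: `id`, `mrs`; attributes `k` and
#'   `component_taxa`.
#' @export
compute_mrs <- function(shap, selected_taxa) {
  if (length(selected_taxa) < 1) abort("need at least one component taxon")
  unknown <- setdiff(selected_taxa, colnames(shap$values))
  if (length(unknown) > 0) {
    abort(paste0("unknown taxa in selection: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  s <- shap$values[, selected_taxa, drop = FALSE] > 0
  out <- tibble(id = shap$ids, mrs = as.integer(rowSums(s)))
  attr(out, "k") <- length(selected_taxa)
  attr(out, "component_taxa") <- selected_taxa
  class(out) <- c("mrs_score", class(out))
  out
}

#' Median split of the risk score
#'
#' Adds a `risk_group` factor: `"high"` for scores strictly above the cohort
#' median, `"low"` otherwise — scores equal to the median go to the low
#' group (a median of 5 yields the partition MRS > 5 vs MRS <= 5).
#'
#' @param mrs An `mrs_score` tibble (or any tibble with an `mrs` column).
#' @return The input with `risk_group` added; `attr(, "mrs_median")` holds
#'   the threshold.
#' @export
median_split <- function(mrs) {
  if (nrow(mrs) == 0) abort("empty score table")
  med <- median(mrs$mrs)
  grp <- factor(ifelse(mrs$mrs > med, "high", "low"),
                levels = c("low", "high"))
  if (all(grp == "low")) {
    warn("all scores are at or below the median; high-risk group is empty")
  }
  out <- mutate(mrs, risk_group = grp)
  attr(out, "mrs_median") <- med
  preserve_mrs_attrs(out, mrs)
}

#' Quartile bins of the risk score
#'
#' Cuts scores at the empirical 25/50/75 percentiles
#' (linear-interpolation quantile definition). Values tied with a boundary
#' are assigned to the lower quartile, so heavy ties never straddle a
#' boundary. Q1 serves as the reference stratum in association models.
#'
#' @param mrs An `mrs_score` tibble.
#' @return The input with a `quartile` factor (`Q1`..`Q4`) added;
#'   `attr(, "cuts")` holds the three cut points.
#' @export
quartile_bins <- function(mrs) {
  x <- mrs$mrs
  if (length(unique(x)) < 2) {
    abort("fewer than 2 distinct score values; quartiles undefined")
  }
  cuts <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  q <- factor(paste0("Q", 1L + (x > cuts[1]) + (x > cuts[2]) + (x > cuts[3])),
              levels = paste0("Q", 1:4))
  out <- mutate(mrs, quartile = q)
  attr(out, "cuts") <- cuts
  preserve_mrs_attrs(out, mrs)
}

preserve_mrs_attrs <- function(out, mrs) {
  attr(out, "k") <- attr(mrs, "k")
  attr(out, "component_taxa") <- attr(mrs, "component_taxa")
  class(out) <- unique(c("mrs_score", class(out)))
  out
}
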