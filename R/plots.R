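#' Plot helpers
#'
#' ggplot2 displays for each result type: `plot_roc()` overlays per-family
#' ROC curves; `plot_importance()` is the mean-|attribution| bar chart;
#' `plot_shap_summary()` the per-individual attribution beeswarm coloured by
#' feature value; `plot_dependence()` an attribution-versus-value profile
#' with its zero-crossing; `plot_volcano()` the metabolite volcano
#' (log2 fold change versus -log10 p) with SDM flags; `plot_forest()` the
#' odds-ratio forest plot. `autoplot()` methods dispatch to these.
#'
#' @param x A bench, importance/shap, dependence, SDM or association object.
#' @param top_n Number of features shown in importance/summary plots.
#' @name mrs-plots
NULL

#' @rdname mrs-plots
#' @param bench An `mrs_bench`.
#' @export
plot_roc <- function(bench) {
  df <- purrr::imap_dfr(bench$roc, function(r, fam) {
    mutate(r$roc, family = sprintf("%s (AUC %.3f)", fam, r$auc))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr,
                                   colour = .data$family)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  colour = NULL, title = "Held-out ROC by classifier family") +
    ggplot2::theme_minimal()
}

#' @rdname mrs-plots
#' @param ranking An `mrs_importance` tibble.
#' @export
plot_importance <- function(ranking, top_n = 20) {
  df <- head(ranking, top_n)
  ggplot2::ggplot(df, ggplot2::aes(.data$importance,
                                   stats::reorder(.data$feature,
                                                  .data$importance))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean |attribution| (margin units)", y = NULL,
                  title = paste("Top", nrow(df), "features")) +
    ggplot2::theme_minimal()
}

#' @rdname mrs-plots
#' @param shap An `mrs_shap`.
#' @param X Cohort or feature matrix used for colouring by feature value.
#' @export
plot_shap_summary <- function(shap, X, top_n = 20) {
  top <- head(rank_importance(shap), top_n)$feature
  Xm <- if (is.matrix(X)) X else
    as.matrix(as.data.frame(X)[, shap$features, drop = FALSE])
  df <- purrr::map_dfr(top, function(f) {
    v <- Xm[, f]
    rng <- range(v)
    tibble(feature = f, attribution = shap$values[, f],
           value_scaled = if (diff(rng) == 0) 0.5 else
             (v - rng[1]) / diff(rng))
  })
  df$feature <- factor(df$feature, levels = rev(top))
  ggplot2::ggplot(df, ggplot2::aes(.data$attribution, .data$feature,
                                   colour = .data$value_scaled)) +
    ggplot2::geom_jitter(height = 0.25, size = 0.4, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::scale_colour_gradient(low = "#3b4cc0", high = "#b40426",
                                   name = "feature value\n(scaled)") +
    ggplot2::labs(x = "attribution (margin units)", y = NULL,
                  title = "Attribution summary") +
    ggplot2::theme_minimal()
}

#' @rdname mrs-plots
#' @param dep A tibble from [dependence_table()].
#' @export
plot_dependence <- function(dep) {
  p <- ggplot2::ggplot(dep, ggplot2::aes(.data$value, .data$attribution)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.5, colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "feature value", y = "attribution",
                  title = "Dependence profile") +
    ggplot2::theme_minimal()
  zc <- attr(dep, "zero_crossing")
  if (!is.null(zc) && is.finite(zc)) {
    p <- p + ggplot2::geom_vline(xintercept = zc, linetype = "dashed")
  }
  p
}

#' @rdname mrs-plots
#' @param sdm An `mrs_sdm` tibble.
#' @export
plot_volcano <- function(sdm) {
  df <- mutate(sdm, neglog_p = -log10(pmax(.data$p_value, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_fc, .data$neglog_p,
                                   colour = .data$sdm)) +
    ggplot2::geom_point(size = 1, alpha = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 name = "SDM") +
    ggplot2::labs(x = "log2 fold change (case / control)",
                  y = "-log10 p", title = "Metabolite volcano") +
    ggplot2::theme_minimal()
}

#' @rdname mrs-plots
#' @param assoc An `mrs_association` tibble.
#' @export
plot_forest <- function(assoc) {
  df <- mutate(assoc,
               label = ifelse(is.na(.data$level), .data$exposure,
                              paste(.data$exposure, .data$level)),
               label = paste(.data$label, .data$model))
  ggplot2::ggplot(df, ggplot2::aes(.data$or, .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2, colour = "grey30") +
    ggplot2::geom_point(colour = "firebrick", size = 1.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI, log scale)", y = NULL,
                  title = "Outcome associations") +
    ggplot2::theme_minimal()
}

#' @rdname mrs-plots
#' @param object Object to plot.
#' @param ... Passed to the underlying `plot_*` function.
#' @method autoplot mrs_bench
#' @export
autoplot.mrs_bench <- function(object, ...) plot_roc(object)

#' @rdname mrs-plots
#' @method autoplot mrs_importance
#' @export
autoplot.mrs_importance <- function(object, ...) plot_importance(object, ...)

#' @rdname mrs-plots
#' @method autoplot mrs_sdm
#' @export
autoplot.mrs_sdm <- function(object, ...) plot_volcano(object)

#' @rdname mrs-plots
#' @method autoplot mrs_association
#' @export
autoplot.mrs_association <- function(object, ...) plot_forest(object)

#' @rdname mrs-plots
#' @method autoplot mrs_ordination
#' @export
autoplot.mrs_ordination <- function(object, ...) {
  df <- object$scores
  ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2)) +
    ggplot2::geom_point(size = 1, alpha = 0.7, colour = "steelblue") +
    ggplot2::labs(
      x = sprintf("axis 1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("axis 2 (%.1f%%)", 100 * object$var_explained[2]),
      title = paste("Ordination:", object$method)) +
    ggplot2::theme_minimal()
}
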