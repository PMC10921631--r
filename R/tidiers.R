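#' Broom-style tidiers
#'
#' `tidy()` returns one row per estimated quantity; `glance()` a one-row
#' model summary.
#'
#' @param x A fitted or result object from this package.
#' @param ... Unused.
#' @name mrs-tidiers
NULL

#' @rdname mrs-tidiers
#' @method tidy mrs_bench
#' @export
tidy.mrs_bench <- function(x, ...) x$results

#' @rdname mrs-tidiers
#' @method glance mrs_bench
#' @export
glance.mrs_bench <- function(x, ...) {
  tibble(best_family = x$results$family[1], best_auc = x$results$auc[1],
         n_families = nrow(x$results), n_train = x$results$n_train[1],
         n_test = x$results$n_test[1], seed = x$seed)
}

#' @rdname mrs-tidiers
#' @method glance mrs_classifier
#' @export
glance.mrs_classifier <- function(x, ...) {
  tibble(family = x$family, n_features = length(x$features),
         hyperparameters = paste(x$tuning$parameter,
                                 signif(x$tuning$value, 4),
                                 sep = "=", collapse = ", "),
         seed = x$seed)
}

#' @rdname mrs-tidiers
#' @method tidy mrs_shap
#' @export
tidy.mrs_shap <- function(x, ...) {
  as_tibble(x$values, rownames = NA) %>%
    mutate(id = x$ids) %>%
    tidyr::pivot_longer(-"id", names_to = "feature",
                        values_to = "attribution")
}

#' @rdname mrs-tidiers
#' @method glance mrs_shap
#' @export
glance.mrs_shap <- function(x, ...) {
  tibble(n = nrow(x$values), n_features = ncol(x$values),
         base_value = x$base_value, method = x$method)
}

#' @rdname mrs-tidiers
#' @method tidy mrs_roc
#' @export
tidy.mrs_roc <- function(x, ...) x$roc

#' @rdname mrs-tidiers
#' @method glance mrs_roc
#' @export
glance.mrs_roc <- function(x, ...) {
  tibble(auc = x$auc, n_case = x$n_case, n_control = x$n_control)
}

#' @rdname mrs-tidiers
#' @method glance mrs_score
#' @export
glance.mrs_score <- function(x, ...) {
  tibble(n = nrow(x), k = attr(x, "k"), mean = mean(x$mrs),
         median = median(x$mrs), min = min(x$mrs), max = max(x$mrs))
}
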