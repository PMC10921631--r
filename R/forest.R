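#' Flattened tree-ensemble representation
#'
#' `shap_forest()` builds the package's internal representation of an additive
#' tree ensemble: the prediction margin is the sum of one leaf value per tree.
#' All attribution code (exact interventional Shapley values, margin
#' evaluation) runs on this structure, so any model that can be expressed as
#' an additive forest gets exact attributions. Converters are provided for
#' fitted xgboost boosters and ranger probability forests.
#'
#' @param trees A list of per-tree data frames with columns `feature`
#'   (1-based feature index, `NA` for a leaf), `split`, `yes`, `no`
#'   (1-based *within-tree* row indices of the children) and `value`
#'   (leaf value; ignored for internal nodes).
#' @param feature_names Character vector naming the feature space; split
#'   `feature` indices refer into it.
#' @param leq Comparison convention: if `TRUE` a case routes to `yes` when
#'   `x <= split` (ranger); if `FALSE` when `x < split` (xgboost).
#' @return An object of class `shap_forest`.
#' @export
shap_forest <- function(trees, feature_names, leq = FALSE) {
  stopifnot(is.list(trees), length(trees) > 0, is.character(feature_names))
  offs <- cumsum(c(0L, vapply(trees, nrow, 1L)))
  feat <- integer(0); spl <- numeric(0); yes <- integer(0); no <- integer(0)
  val <- numeric(0)
  for (t in seq_along(trees)) {
    tr <- trees[[t]]
    need <- c("feature", "split", "yes", "no", "value")
    if (!all(need %in% names(tr))) {
      abort(paste0("tree ", t, " is missing columns: ",
                   paste(setdiff(need, names(tr)), collapse = ", ")))
    }
    leaf <- is.na(tr$feature)
    fi <- ifelse(leaf, -1L, as.integer(tr$feature) - 1L)
    if (any(fi[!leaf] < 0L | fi[!leaf] >= length(feature_names))) {
      abort(paste0("tree ", t, " references a feature outside feature_names"))
    }
    feat <- c(feat, fi)
    spl <- c(spl, ifelse(leaf, 0, tr$split))
    yes <- c(yes, ifelse(leaf, -1L, as.integer(tr$yes) - 1L + offs[t]))
    no <- c(no, ifelse(leaf, -1L, as.integer(tr$no) - 1L + offs[t]))
    val <- c(val, ifelse(leaf, tr$value, 0))
  }
  structure(
    list(feature = feat, split = spl, yes = yes, no = no, value = val,
         roots = offs[-length(offs)], leq = isTRUE(leq),
         feature_names = feature_names),
    class = "shap_forest")
}

#' @export
print.shap_forest <- function(x, ...) {
  cat("<shap_forest> ", length(x$roots), " trees, ",
      length(x$feature_names), " features, ",
      sum(x$feature < 0L), " leaves\n", sep = "")
  invisible(x)
}

#' Evaluate the margin of a flattened forest
#'
#' Sums the leaf value reached in every tree, in double precision. For
#' boosted classifiers this is the log-odds margin; for probability forests
#' the class-1 probability.
#'
#' @param forest A [shap_forest()].
#' @param X Numeric matrix (cases x features) in the forest's feature order.
#' @return Numeric vector of margins, one per row of `X`.
#' @export
forest_predict <- function(forest, X) {
  stopifnot(inherits(forest, "shap_forest"))
  X <- as.matrix(X)
  if (ncol(X) != length(forest$feature_names)) {
    abort("X has the wrong number of columns for this forest")
  }
  if (any(!is.finite(X))) abort("non-finite feature values are not supported")
  forest_predict_cpp(X, forest$feature, forest$split, forest$yes, forest$no,
                     forest$value, forest$roots, forest$leq)
}

## -- converters ------------------------------------------------------------

as_shap_forest <- function(x, ...) UseMethod("as_shap_forest")

#' @export
as_shap_forest.shap_forest <- function(x, ...) x

# xgboost booster -> shap_forest. Requires the booster to have been trained
# with feature names and base_score 0.5 (zero margin offset), which
# train_classifier() guarantees.
#' @export
as_shap_forest.xgb.Booster <- function(x, feature_names = NULL, ...) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = x))
  value_col <- intersect(c("Gain", "Quality"), names(dt))[1]
  feature_names <- feature_names %||% setdiff(unique(dt$Feature), "Leaf")
  trees <- lapply(split(dt, dt$Tree), function(tr) {
    idx <- setNames(seq_len(nrow(tr)), tr$ID)
    leaf <- tr$Feature == "Leaf"
    data.frame(
      feature = ifelse(leaf, NA_integer_, match(tr$Feature, feature_names)),
      split = ifelse(leaf, NA_real_, tr$Split),
      yes = ifelse(leaf, NA_integer_, unname(idx[tr$Yes])),
      no = ifelse(leaf, NA_integer_, unname(idx[tr$No])),
      value = ifelse(leaf, tr[[value_col]], NA_real_))
  })
  if (anyNA(unlist(lapply(trees, function(t) t$feature[!is.na(t$split)])))) {
    abort("booster uses features absent from feature_names")
  }
  shap_forest(trees, feature_names, leq = FALSE)
}

# ranger probability forest -> shap_forest. Leaf values are the class-1
# probability divided by the number of trees, so the forest margin equals the
# averaged predicted probability.
#' @export
as_shap_forest.ranger <- function(x, positive = "1", ...) {
  if (is.null(x$forest)) abort("ranger model was fitted with write.forest = FALSE")
  fn <- x$forest$independent.variable.names
  pred_col <- paste0("pred.", positive)
  trees <- lapply(seq_len(x$num.trees), function(t) {
    ti <- ranger::treeInfo(x, t)
    if (!pred_col %in% names(ti)) {
      abort(paste0("ranger forest has no class-probability column ", pred_col,
                   "; fit with probability = TRUE and outcome levels c(\"0\",\"1\")"))
    }
    data.frame(
      feature = ifelse(ti$terminal, NA_integer_, match(ti$splitvarName, fn)),
      split = ti$splitval,
      yes = ti$leftChild + 1L,
      no = ti$rightChild + 1L,
      value = ifelse(ti$terminal, ti[[pred_col]] / x$num.trees, NA_real_))
  })
  shap_forest(trees, fn, leq = TRUE)
}

## -- brute-force Shapley oracle --------------------------------------------

#' Exact Shapley values by coalition enumeration
#'
#' Computes interventional Shapley values of
#' \eqn{v(S) = \mathrm{mean}_{r \in background} f(r \text{ with } S \text{ set to } x)}
#' by enumerating all \eqn{2^p} coalitions. Exponential in the number of
#' features, so it refuses more than `max_features`; it exists as an
#' independent oracle against which the fast tree algorithm is validated.
#'
#' @param f A prediction function `function(matrix) -> numeric` margin, or a
#'   [shap_forest()].
#' @param x Numeric feature vector for the case being explained.
#' @param background Numeric matrix of reference rows (same feature order).
#' @param max_features Refusal threshold for the enumeration (default 12).
#' @return Numeric vector of Shapley values, one per feature; their sum equals
#'   `f(x) - mean(f(background))` (efficiency).
#' @export
shapley_bruteforce <- function(f, x, background, max_features = 12) {
  if (inherits(f, "shap_forest")) {
    forest <- f
    f <- function(m) forest_predict(forest, m)
  }
  stopifnot(is.function(f))
  x <- as.numeric(x)
  background <- as.matrix(background)
  p <- length(x)
  if (p > max_features) {
    abort(paste0("brute-force enumeration refused for p = ", p,
                 " features (max_features = ", max_features, ")"))
  }
  stopifnot(ncol(background) == p)
  n_mask <- bitwShiftL(1L, p)
  v <- numeric(n_mask)
  for (mask in 0:(n_mask - 1L)) {
    Z <- background
    for (j in seq_len(p)) {
      if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0L) Z[, j] <- x[j]
    }
    v[mask + 1L] <- mean(f(Z))
  }
  popcount <- vapply(0:(n_mask - 1L), function(m) {
    sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) != 0L)
  }, 1L)
  w <- function(s) 1 / (p * choose(p - 1, s))
  phi <- numeric(p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(0:(n_mask - 1L), bit) == 0L) - 1L
    for (mask in without) {
      s <- popcount[mask + 1L]
      phi[j] <- phi[j] + w(s) * (v[mask + bit + 1L] - v[mask + 1L])
    }
  }
  phi
}
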