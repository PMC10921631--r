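#' Stratified train/test split
#'
#' Partitions a cohort into disjoint, exhaustive train and test sets with the
#' outcome ratio preserved per class (allocation by per-class rounding).
#'
#' @param cohort Cohort tibble with a binary `nafld` column.
#' @param ratio Fraction of each class assigned to the training set.
#' @param seed Integer seed controlling the within-class shuffles.
#' @return A list with `train` and `test` cohort tibbles.
#' @export
split_cohort <- function(cohort, ratio = 0.8, seed = 1L) {
  if (ratio <= 0 || ratio >= 1) abort("ratio must lie strictly in (0, 1)")
  y <- cohort$nafld
  if (length(unique(y)) < 2) abort("both outcome classes must be present")
  set.seed(seed)
  train_idx <- unlist(lapply(split(seq_along(y), y), function(idx) {
    k <- round(ratio * length(idx))
    sample(idx, k)
  }), use.names = FALSE)
  train <- cohort[sort(train_idx), , drop = FALSE]
  test <- cohort[setdiff(seq_along(y), train_idx), , drop = FALSE]
  for (part in list(train = train, test = test)) {
    if (length(unique(part$nafld)) < 2) {
      abort(paste0("a class is absent from one side of the split at ratio ",
                   ratio, "; use a larger cohort or a less extreme ratio"))
    }
  }
  list(train = restore_cohort_attrs(train, cohort),
       test = restore_cohort_attrs(test, cohort))
}

restore_cohort_attrs <- function(x, template) {
  attr(x, "covariate_names") <- attr(template, "covariate_names")
  attr(x, "taxa_names") <- attr(template, "taxa_names")
  attr(x, "truth") <- attr(template, "truth")
  class(x) <- unique(c("mrs_cohort", class(x)))
  x
}

#' Train one probabilistic classifier family
#'
#' Fits one of four model families on the cohort's covariate + taxa feature
#' matrix with cross-validated tuning over a small documented grid:
#'
#' * `"gbt"` — gradient-boosted trees (xgboost, logistic objective, row
#'   subsample 0.8 and per-tree feature subsample 0.3). Rounds are capped at
#'   `max_boost_rounds` with early stopping (patience 100) on the
#'   cross-validated log loss; when `tune = TRUE` the grid spans tree depths
#'   1/2/4 at learning rate 0.05.
#' * `"rf"` — probability random forest (ranger, 500 trees); `mtry` selected
#'   by the forest's out-of-bag Brier score.
#' * `"svm"` — RBF support-vector machine (e1071) with a cost/gamma grid
#'   scored by internal cross-validated accuracy; probabilities via the
#'   package's own deterministic Platt scaling of the decision values.
#' * `"logistic"` — L2-penalised logistic regression (glmnet, ridge) with the
#'   penalty chosen by `cv.glmnet`.
#'
#' @param data Training cohort tibble.
#' @param family One of `"gbt"`, `"rf"`, `"svm"`, `"logistic"`.
#' @param cv_folds Number of cross-validation folds (>= 2).
#' @param max_boost_rounds Boosting-round cap for `"gbt"`.
#' @param tune If `FALSE`, skip the grid and fit documented defaults (rounds
#'   are still chosen by cross-validated early stopping for `"gbt"`).
#' @param seed Integer seed for fold assignment and any stochastic fitting.
#' @return An object of class `mrs_classifier` supporting
#'   `predict(type = "prob")` and `predict(type = "margin")`.
#' @export
train_classifier <- function(data, family = c("gbt", "rf", "svm", "logistic"),
                             cv_folds = 10, max_boost_rounds = 5000,
                             tune = TRUE, seed = 1L) {
  family <- match.arg(family)
  if (cv_folds < 2) abort("cv_folds must be >= 2")
  X <- feature_matrix(data)
  y <- data$nafld
  if (length(unique(y)) < 2) abort("outcome is constant; cannot train")
  if (any(!is.finite(X))) abort("non-finite feature values in training data")
  fit <- switch(family,
                gbt = fit_gbt(X, y, cv_folds, max_boost_rounds, tune, seed),
                rf = fit_rf(X, y, tune, seed),
                svm = fit_svm(X, y, cv_folds, tune, seed),
                logistic = fit_logistic_ridge(X, y, cv_folds, seed))
  structure(
    c(fit, list(family = family, features = colnames(X), seed = seed,
                X_train = X)),
    class = "mrs_classifier")
}

fit_gbt <- function(X, y, cv_folds, max_boost_rounds, tune, seed) {
  # row + feature subsampling stabilises boosting when most features carry
  # no signal; shallow trees suit near-additive risk surfaces
  base <- list(subsample = 0.8, colsample_bytree = 0.3)
  grid <- if (tune) {
    list(c(list(eta = 0.05, max_depth = 1), base),
         c(list(eta = 0.05, max_depth = 2), base),
         c(list(eta = 0.05, max_depth = 4), base))
  } else {
    list(c(list(eta = 0.05, max_depth = 2), base))
  }
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  scores <- purrr::map(grid, function(g) {
    params <- c(list(objective = "binary:logistic", base_score = 0.5,
                     nthread = 1, eval_metric = "logloss"), g)
    set.seed(seed)
    cv <- xgboost::xgb.cv(params = params, data = dtrain,
                          nrounds = max_boost_rounds, nfold = cv_folds,
                          early_stopping_rounds = 100, verbose = 0)
    log <- as.data.frame(cv$evaluation_log)
    best <- cv$best_iteration %||% which.min(log$test_logloss_mean)
    list(best_iter = best, loss = log$test_logloss_mean[best])
  })
  best_i <- which.min(vapply(scores, `[[`, 1, "loss"))
  params <- c(list(objective = "binary:logistic", base_score = 0.5,
                   nthread = 1), grid[[best_i]])
  set.seed(seed)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = scores[[best_i]]$best_iter)
  list(fit = booster,
       forest = as_shap_forest(booster, feature_names = colnames(X)),
       tuning = tibble(parameter = c("eta", "max_depth", "nrounds"),
                       value = c(grid[[best_i]]$eta, grid[[best_i]]$max_depth,
                                 scores[[best_i]]$best_iter),
                       cv_logloss = scores[[best_i]]$loss))
}

fit_rf <- function(X, y, tune, seed) {
  p <- ncol(X)
  mtry_grid <- if (tune) unique(c(floor(sqrt(p)), max(2L, floor(p / 5)))) else
    floor(sqrt(p))
  fits <- lapply(mtry_grid, function(m) {
    ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                   probability = TRUE, num.trees = 500, mtry = m,
                   seed = seed, num.threads = 1)
  })
  oob <- vapply(fits, function(f) f$prediction.error, 1)
  best <- which.min(oob)
  list(fit = fits[[best]],
       tuning = tibble(parameter = "mtry", value = mtry_grid[best],
                       cv_logloss = oob[best]))
}

fit_svm <- function(X, y, cv_folds, tune, seed) {
  p <- ncol(X)
  grid <- if (tune) {
    expand.grid(cost = c(1, 10), gamma = c(1 / p, 4 / p))
  } else {
    data.frame(cost = 1, gamma = 1 / p)
  }
  yf <- factor(y, levels = c(0, 1))
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    set.seed(seed)
    e1071::svm(X, yf, kernel = "radial", cost = grid$cost[i],
               gamma = grid$gamma[i], cross = cv_folds)$tot.accuracy
  }, 1)
  best <- which.max(acc)
  fit <- e1071::svm(X, yf, kernel = "radial", cost = grid$cost[best],
                    gamma = grid$gamma[best])
  dv <- drop(attr(predict(fit, X, decision.values = TRUE), "decision.values"))
  platt <- glm(y ~ dv, family = binomial())
  list(fit = fit, platt = coef(platt),
       tuning = tibble(parameter = c("cost", "gamma"),
                       value = c(grid$cost[best], grid$gamma[best]),
                       cv_logloss = NA_real_))
}

fit_logistic_ridge <- function(X, y, cv_folds, seed) {
  set.seed(seed)
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 0,
                          nfolds = cv_folds)
  list(fit = cv,
       tuning = tibble(parameter = "lambda", value = cv$lambda.min,
                       cv_logloss = min(cv$cvm)))
}

#' @export
print.mrs_classifier <- function(x, ...) {
  cat("<mrs_classifier> family:", x$family, "|", length(x$features),
      "features\n")
  print(x$tuning)
  invisible(x)
}

#' Predict from a trained classifier
#'
#' @param object An `mrs_classifier`.
#' @param newdata Cohort tibble or numeric feature matrix.
#' @param type `"prob"` for class-1 probability, `"margin"` for the model's
#'   native margin (log-odds for `gbt`/`svm`/`logistic`, probability for `rf`).
#' @param ... Unused.
#' @export
predict.mrs_classifier <- function(object, newdata,
                                   type = c("prob", "margin"), ...) {
  type <- match.arg(type)
  X <- classifier_features(object, newdata)
  margin <- switch(
    object$family,
    gbt = forest_predict(object$forest, X),
    rf = predict(object$fit, data = X, num.threads = 1)$predictions[, "1"],
    svm = {
      dv <- drop(attr(predict(object$fit, X, decision.values = TRUE),
                      "decision.values"))
      unname(object$platt[1] + object$platt[2] * dv)
    },
    logistic = drop(predict(object$fit, newx = X, s = "lambda.min",
                            type = "link")))
  if (type == "margin") return(as.numeric(margin))
  if (object$family == "rf") return(as.numeric(margin))
  as.numeric(plogis(margin))
}

classifier_features <- function(object, newdata) {
  X <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  missing <- setdiff(object$features, colnames(X))
  if (length(missing) > 0) {
    abort(paste0("newdata lacks model features: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  X <- X[, object$features, drop = FALSE]
  if (any(!is.finite(X))) abort("non-finite feature values in newdata")
  X
}

#' ROC curve and AUC
#'
#' Builds the empirical ROC curve (one point per distinct score, ties
#' grouped, so tied scores contribute diagonal segments) and its trapezoidal
#' area, which equals the midrank Mann-Whitney concordance probability.
#'
#' @param model An `mrs_classifier`, or a numeric score vector.
#' @param test Test cohort tibble (when `model` is a classifier), or the 0/1
#'   label vector (when `model` is a score vector).
#' @return A list of class `mrs_roc`: `auc`, `roc` (tibble with `threshold`,
#'   `fpr`, `tpr`), `n_case`, `n_control`.
#' @export
evaluate_roc_auc <- function(model, test) {
  if (inherits(model, "mrs_classifier")) {
    scores <- predict(model, test, type = "prob")
    labels <- test$nafld
  } else {
    scores <- as.numeric(model)
    labels <- as.numeric(test)
  }
  if (length(scores) == 0) abort("empty test set")
  if (length(unique(labels)) < 2) {
    abort("test set contains a single outcome class; AUC undefined")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(1 - l)
  last <- !duplicated(grp, fromLast = TRUE)
  n1 <- sum(l); n0 <- sum(1 - l)
  roc <- tibble(threshold = c(Inf, s[last]),
                fpr = c(0, fp[last] / n0),
                tpr = c(0, tp[last] / n1))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  structure(list(auc = auc, roc = roc, n_case = n1, n_control = n0),
            class = "mrs_roc")
}

#' @export
print.mrs_roc <- function(x, ...) {
  cat("<mrs_roc> AUC =", round(x$auc, 4), "(", x$n_case, "cases /",
      x$n_control, "controls )\n")
  invisible(x)
}

#' Benchmark classifier families on one shared split
#'
#' Trains the requested families on the same stratified 80/20 (by default)
#' split and reports held-out ROC/AUC per family, ranked by test AUC.
#' Duplicate family requests are collapsed with a warning.
#'
#' @inheritParams train_classifier
#' @param cohort Cohort tibble.
#' @param families Character vector of families to compare (>= 2).
#' @param ratio Train fraction for [split_cohort()].
#' @return An object of class `mrs_bench`: `$results` (tibble ranked by AUC),
#'   `$roc` (named list of `mrs_roc`), `$models` (named list of classifiers),
#'   `$split` (the train/test list), `$seed`.
#' @export
compare_models <- function(cohort, families = c("gbt", "rf", "svm", "logistic"),
                           ratio = 0.8, cv_folds = 10,
                           max_boost_rounds = 5000, tune = TRUE, seed = 1L) {
  if (anyDuplicated(families)) {
    warn("duplicate families requested; keeping one of each")
    families <- unique(families)
  }
  if (length(families) < 2) abort("need at least two families to compare")
  split <- split_cohort(cohort, ratio = ratio, seed = seed)
  models <- purrr::map(setNames(families, families), function(fam) {
    train_classifier(split$train, family = fam, cv_folds = cv_folds,
                     max_boost_rounds = max_boost_rounds, tune = tune,
                     seed = seed)
  })
  roc <- purrr::map(models, evaluate_roc_auc, test = split$test)
  results <- tibble(
    family = families,
    auc = vapply(roc, `[[`, 1, "auc"),
    n_train = nrow(split$train), n_test = nrow(split$test),
    hyperparameters = vapply(models, function(m) {
      paste(m$tuning$parameter, signif(m$tuning$value, 4),
            sep = "=", collapse = ", ")
    }, "")) %>%
    arrange(desc(.data$auc))
  structure(list(results = results, roc = roc, models = models,
                 split = split, seed = seed),
            class = "mrs_bench")
}

#' @export
print.mrs_bench <- function(x, ...) {
  cat("<mrs_bench> seed", x$seed, "| best family:", x$results$family[1], "\n")
  print(x$results)
  invisible(x)
}
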