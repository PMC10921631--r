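test_that("stratified split partitions exactly and reproducibly", {
  co <- make_toy_cohort(n = 10, seed = 2)
  sp <- split_cohort(co, ratio = 0.8, seed = 4)
  expect_equal(nrow(sp$train), 8)
  expect_equal(nrow(sp$test), 2)
  expect_setequal(c(sp$train$id, sp$test$id), co$id)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  sp2 <- split_cohort(co, ratio = 0.8, seed = 4)
  expect_identical(sp$train$id, sp2$train$id)

  # class-proportional allocation: 56 cases of 100 at 0.8 -> 44-45 in train
  co2 <- make_toy_cohort(n = 100, sep = FALSE, seed = 6)
  co2$nafld <- c(rep(1L, 56), rep(0L, 44))
  sp3 <- split_cohort(co2, ratio = 0.8, seed = 1)
  expect_true(sum(sp3$train$nafld) %in% 44:45)
  expect_lt(abs(mean(sp3$train$nafld) - 0.56), 1 / nrow(sp3$train) + 1e-9)

  expect_error(split_cohort(co, ratio = 1.2), "strictly in")
  co3 <- make_toy_cohort(n = 6, sep = FALSE, seed = 1)
  co3$nafld <- c(1L, rep(0L, 5))
  expect_error(split_cohort(co3, ratio = 0.5, seed = 1), "absent")
})

test_that("ROC/AUC handles perfect, discordant-pair and tied scores", {
  expect_equal(evaluate_roc_auc(c(0, 1, 1, 0), c(0, 1, 1, 0))$auc, 1.0)
  expect_equal(evaluate_roc_auc(c(0.9, 0.8, 0.3), c(1, 0, 1))$auc, 0.5)
  expect_equal(evaluate_roc_auc(rep(0.5, 20), rep(0:1, 10))$auc, 0.5)
  expect_error(evaluate_roc_auc(runif(5), rep(1, 5)), "single outcome class")
  r <- evaluate_roc_auc(c(0.2, 0.4, 0.9), c(0, 1, 1))
  expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
})

test_that("trapezoidal AUC equals the midrank Mann-Whitney statistic", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), sample(c(1, 2, 6), 1)) # induce ties sometimes
    expect_equal(evaluate_roc_auc(scores, labels)$auc,
                 auc_mann_whitney(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- runif(150)
  labels <- rbinom(150, 1, plogis(3 * scores - 1.5))
  expect_equal(evaluate_roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-9)
})

test_that("every family separates a linearly separable toy", {
  co <- make_toy_cohort(n = 200, sep = TRUE, seed = 5)
  for (fam in c("gbt", "rf", "svm", "logistic")) {
    m <- suppressWarnings(
      train_classifier(co, fam, cv_folds = 3, max_boost_rounds = 200,
                       tune = FALSE, seed = 1))
    acc <- mean((predict(m, co) > 0.5) == co$nafld)
    expect_gte(acc, 0.95)
  }
})

test_that("training refuses degenerate inputs", {
  co <- make_toy_cohort(n = 50, seed = 1)
  co$nafld <- rep(1L, 50)
  expect_error(train_classifier(co, "gbt"), "constant")
  co2 <- make_toy_cohort(n = 50, seed = 1)
  co2$x1[3] <- NA_real_
  expect_error(train_classifier(co2, "logistic"), "non-finite")
  expect_error(train_classifier(make_toy_cohort(60), "gbt", cv_folds = 1),
               "cv_folds")
})

test_that("forest margins match the fitted boosters and forests", {
  co <- simulate_cohort(small_sim_config(n = 250, seed = 2))
  sp <- split_cohort(co, 0.8, seed = 2)
  m <- train_classifier(sp$train, "gbt", cv_folds = 3, max_boost_rounds = 150,
                        tune = FALSE, seed = 2)
  X <- feature_matrix(sp$test)
  expect_lt(max(abs(predict(m, X, type = "margin") -
                      predict(m$fit, xgboost::xgb.DMatrix(X),
                              outputmargin = TRUE))), 1e-5)
  rf <- train_classifier(sp$train, "rf", cv_folds = 3, tune = FALSE, seed = 2)
  forest <- mrscore:::as_shap_forest.ranger(rf$fit)
  expect_lt(max(abs(forest_predict(forest, X) - predict(rf, X))), 1e-10)
})

test_that("a label-permuted cohort yields chance-level AUC for all families", {
  co <- simulate_cohort(small_sim_config(n = 1000, seed = 7))
  set.seed(99)
  co$nafld <- sample(co$nafld)
  bench <- suppressWarnings(
    compare_models(co, ratio = 0.5, cv_folds = 3, max_boost_rounds = 150,
                   tune = FALSE, seed = 3))
  expect_true(all(bench$results$auc > 0.4 & bench$results$auc < 0.6))
})

test_that("compare_models dedupes families and ranks by AUC on one split", {
  co <- make_toy_cohort(n = 150, sep = TRUE, seed = 4)
  expect_warning(
    bench <- compare_models(co, families = c("gbt", "gbt", "logistic"),
                            cv_folds = 3, max_boost_rounds = 100,
                            tune = FALSE, seed = 1),
    "duplicate")
  expect_equal(sort(bench$results$family), c("gbt", "logistic"))
  expect_true(all(diff(bench$results$auc) <= 0))
  expect_equal(bench$results$n_test[1], nrow(bench$split$test))
  expect_error(compare_models(co, families = "gbt"), "two families")
  td <- tidy(bench)
  expect_s3_class(td, "tbl_df")
  expect_equal(glance(bench)$best_family, bench$results$family[1])
})

test_that("the bench is bit-reproducible under a fixed seed", {
  co <- simulate_cohort(small_sim_config(n = 300, seed = 12))
  b1 <- compare_models(co, families = c("gbt", "logistic"), cv_folds = 3,
                       max_boost_rounds = 100, tune = FALSE, seed = 5)
  b2 <- compare_models(co, families = c("gbt", "logistic"), cv_folds = 3,
                       max_boost_rounds = 100, tune = FALSE, seed = 5)
  expect_identical(b1$results$auc, b2$results$auc)
  expect_identical(predict(b1$models$gbt, co), predict(b2$models$gbt, co))
})
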