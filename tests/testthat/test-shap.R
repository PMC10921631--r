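test_that("brute-force Shapley satisfies the axioms on simple games", {
  B <- matrix(rnorm(40), 8, 5)
  # dummy axiom: constant model attributes nothing
  phi <- shapley_bruteforce(function(m) rep(2.5, nrow(m)), rnorm(5), B)
  expect_equal(phi, rep(0, 5), tolerance = 1e-12)
  # additive game: attribution_j = v({j}) - v(empty)
  x <- rnorm(5)
  phi_lin <- shapley_bruteforce(function(m) rowSums(m), x, B)
  expect_equal(phi_lin, x - colMeans(B), tolerance = 1e-10)
  # efficiency on a random forest fixture
  forest <- random_forest_fixture(p = 5, n_trees = 4, depth = 3, seed = 2)
  phi_f <- shapley_bruteforce(forest, x, B)
  expect_equal(sum(phi_f),
               forest_predict(forest, matrix(x, 1)) -
                 mean(forest_predict(forest, B)),
               tolerance = 1e-10)
  expect_error(shapley_bruteforce(function(m) rowSums(m), rnorm(15),
                                  matrix(rnorm(150), 10)), "refused")
})

test_that("exact tree attributions match the enumeration oracle", {
  for (s in 1:10) {
    p <- sample(3:8, 1)
    forest <- random_forest_fixture(p, n_trees = sample(1:4, 1),
                                    depth = sample(2:3, 1), seed = 100 + s)
    set.seed(200 + s)
    B <- matrix(rnorm(6 * p), 6, p)
    x <- rnorm(p)
    fast <- mrscore:::treeshap_interventional_cpp(
      matrix(x, 1), B, forest$feature, forest$split, forest$yes, forest$no,
      forest$value, forest$roots, forest$leq)
    slow <- shapley_bruteforce(forest, x, B)
    expect_equal(drop(fast), slow, tolerance = 1e-10)
  }
})

test_that("symmetric additive trees give equal attributions to equal values", {
  # one stump per feature, mirrored: f(x) = 1[x1 > 0] + 1[x2 > 0]
  stump <- function(feat) {
    data.frame(feature = c(feat, NA, NA), split = c(0, NA, NA),
               yes = c(2, NA, NA), no = c(3, NA, NA),
               value = c(NA, 0, 1))
  }
  forest <- shap_forest(list(stump(1L), stump(2L)), c("f1", "f2"))
  B <- cbind(f1 = c(-1, 1, 2, -2), f2 = c(1, -1, -2, 2)) # exchangeable
  phi <- mrscore:::treeshap_interventional_cpp(
    matrix(c(3, 3), 1), B, forest$feature, forest$split, forest$yes,
    forest$no, forest$value, forest$roots, forest$leq)
  expect_equal(phi[1, 1], phi[1, 2], tolerance = 1e-12)
})

test_that("attributions are locally accurate for every family", {
  co <- simulate_cohort(small_sim_config(n = 250, seed = 4))
  sp <- split_cohort(co, 0.8, seed = 4)
  for (fam in c("gbt", "rf", "logistic")) {
    m <- train_classifier(sp$train, fam, cv_folds = 3,
                          max_boost_rounds = 100, tune = FALSE, seed = 4)
    sh <- shap_attribute(m, sp$test, n_background = 64, seed = 4)
    marg <- predict(m, sp$test, type = "margin")
    expect_lt(max(abs(rowSums(sh$values) + sh$base_value - marg)), 1e-6)
  }
})

test_that("permutation sampling attributes a non-tree model coherently", {
  co <- make_toy_cohort(n = 120, sep = TRUE, seed = 9)
  m <- suppressWarnings(train_classifier(co, "svm", cv_folds = 3,
                                         tune = FALSE, seed = 1))
  sub <- co[1:10, ]
  bg <- feature_matrix(co)[1:16, ]
  sh <- shap_attribute(m, sub, background = bg, n_perm = 32, seed = 2)
  expect_identical(sh$method, "permutation")
  # with the background cycled a whole number of times, efficiency is exact
  marg <- predict(m, sub, type = "margin")
  expect_lt(max(abs(rowSums(sh$values) + sh$base_value - marg)), 1e-8)
  # the separating features dominate the constantly irrelevant composition
  imp <- rank_importance(sh)
  expect_setequal(imp$feature[1:2], c("x1", "x2"))
})

test_that("a feature the model never uses gets zero attribution", {
  forest <- shap_forest(list(data.frame(
    feature = c(1L, NA, NA), split = c(0.5, NA, NA),
    yes = c(2, NA, NA), no = c(3, NA, NA),
    value = c(NA, -1, 1))), c("f1", "f2", "f3"))
  set.seed(5)
  B <- matrix(rnorm(30), 10, 3)
  phi <- mrscore:::treeshap_interventional_cpp(
    matrix(rnorm(3), 1), B, forest$feature, forest$split, forest$yes,
    forest$no, forest$value, forest$roots, forest$leq)
  expect_identical(phi[1, 2], 0)
  expect_identical(phi[1, 3], 0)
})

test_that("importance ranks by mean absolute attribution with name ties", {
  sh <- structure(list(values = matrix(c(1, -1, 0, 0, 2, 2), 2,
                                       dimnames = list(NULL,
                                                       c("f1", "f2", "f3"))),
                       base_value = 0, features = c("f1", "f2", "f3"),
                       ids = c("a", "b"), method = "tree"),
                  class = "mrs_shap")
  r <- rank_importance(sh)
  expect_equal(r$feature, c("f3", "f1", "f2"))
  expect_equal(r$importance, c(2, 1, 0))
  # exact importance tie -> alphabetical
  sh$values <- matrix(c(1, -1, -1, 1), 2,
                      dimnames = list(NULL, c("fb", "fa")))
  sh$features <- c("fb", "fa")
  expect_equal(rank_importance(sh)$feature, c("fa", "fb"))
})

test_that("top-k selection returns the taxa subset among the top features", {
  r <- tibble::tibble(feature = c("taxon_002", "BMI", "taxon_001", "age"),
                      importance = c(4, 3, 2, 1), rank = 1:4)
  class(r) <- c("mrs_importance", class(r))
  expect_equal(select_top_k(r, k = 4),
               list(features = r$feature,
                    taxa = c("taxon_002", "taxon_001")))
  expect_equal(select_top_k(r, k = 1)$taxa, "taxon_002")
  expect_equal(select_top_k(r, k = 2, taxa = c("BMI"))$taxa, "BMI")
  expect_error(select_top_k(r, k = 0), "positive")
  expect_error(select_top_k(r, k = 9), "exceeds")
})

test_that("dependence profiles locate thresholds and flag degeneracies", {
  set.seed(6)
  n <- 300
  v <- sort(runif(n, -2, 2))
  sh <- structure(list(
    values = cbind(sig = v - 0.5 + rnorm(n, 0, 0.05),
                   null = rnorm(n, 0, 1e-3), flat = rep(0, n)),
    base_value = 0, features = c("sig", "null", "flat"),
    ids = as.character(1:n), method = "tree"), class = "mrs_shap")
  X <- cbind(sig = v, null = runif(n), flat = rep(1, n))
  dep <- dependence_table(sh, X, "sig")
  zc <- attr(dep, "zero_crossing")
  expect_true(is.finite(zc) && abs(zc - 0.5) < 0.3)
  expect_true(all(dep$smoothed[dep$value > zc + 0.3] > 0))
  expect_false(attr(dep, "degenerate"))
  expect_true(all(diff(dep$value) >= 0))
  expect_warning(dep_flat <- dependence_table(sh, X, "flat"), "constant")
  expect_true(attr(dep_flat, "degenerate"))
  expect_error(dependence_table(sh, X, "nope"), "unknown feature")
})
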