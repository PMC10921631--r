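test_that("log transform and autoscaling behave as stated", {
  m <- matrix(c(0, 1, 3, 7), 2, dimnames = list(c("a", "b"), c("m1", "m2")))
  y <- log_normalize(m, pseudocount = 1)
  expect_identical(y["a", "m1"], 0)
  expect_equal(log_normalize(2 * m + 0, pseudocount = 0)[2, ] -
                 log_normalize(m + 0, pseudocount = 0)[2, ],
               c(m1 = log(2), m2 = log(2)))
  set.seed(4)
  big <- matrix(rlnorm(200), 20, 10,
                dimnames = list(NULL, paste0("m", 1:10)))
  ya <- log_normalize(big, autoscale = TRUE)
  expect_lt(max(abs(colMeans(ya))), 1e-9)
  expect_lt(max(abs(apply(ya, 2, sd) - 1)), 1e-9)
  expect_error(log_normalize(matrix(-1)), "non-negative")
})

test_that("BH q-values match the brute-force step-up exactly", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.05, 7)), rep(0.05, 7))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_error(bh_fdr(c(0.2, 1.4)), "\\[0, 1\\]")
  set.seed(9)
  for (i in 1:200) {
    p <- round(runif(sample(1:25, 1)), sample(2:4, 1))
    expect_equal(bh_fdr(p), bh_bruteforce(p), tolerance = 1e-14)
  }
})

test_that("planted fold changes are flagged and nulls are controlled", {
  cfg <- sim_config(n_individuals = 1000, n_taxa = 20,
                    causal_taxa = integer(0), taxa_effects = numeric(0),
                    covariate_effects = numeric(0), prevalence_target = 0.5,
                    metabolite_count = 60, metabolite_subclasses = 5,
                    planted_sdm = data.frame(metabolite = c(5L, 40L),
                                             fold_change = c(2.5, 0.4)),
                    seed = 31)
  co <- simulate_cohort(cfg)
  mets <- simulate_metabolites(co, cfg)
  res <- sdm_screen(mets, case = co$nafld == 1)
  expect_true(res$sdm[5])
  expect_true(res$sdm[40])
  expect_lt(abs(res$log2_fc[5] - log2(2.5)), 0.15)
  expect_lt(res$log2_fc[40], -1)
  expect_lte(sum(res$sdm[-c(5, 40)]), 1)
  expect_identical(res$sdm, res$p_value < 0.05 & res$q_value < 0.1 &
                     abs(res$log2_fc) > 1)
  expect_true("subclass" %in% names(res))
})

test_that("a fold change of exactly 2 fails the strict criterion", {
  control <- rep(c(1, 2, 3, 4, 5), 8)
  case <- 2 * control # mean ratio exactly 2, strongly significant on logs
  m <- matrix(c(case, control), ncol = 1,
              dimnames = list(NULL, "met_001"))
  res <- sdm_screen(m, case = rep(c(TRUE, FALSE), each = 40),
                    pseudocount = 0)
  expect_equal(res$fold_change, 2)
  expect_lt(res$p_value, 0.05)
  expect_false(res$sdm)
})

test_that("screen preconditions and group handling are enforced", {
  m <- matrix(rlnorm(40), 10, 4, dimnames = list(NULL, paste0("m", 1:4)))
  expect_error(sdm_screen(m, rep(TRUE, 10)), "non-empty")
  expect_error(sdm_screen(m, c(TRUE, rep(FALSE, 9))), "at least 2")
  welch <- sdm_screen(m, rep(c(TRUE, FALSE), 5), welch = TRUE)
  expect_s3_class(welch, "mrs_sdm")
})

test_that("Spearman rho handles monotone, tied and degenerate input", {
  expect_equal(spearman_assoc(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_assoc(1:10, -(1:10))$rho, -1)
  r <- spearman_assoc(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$rho, 0.6, tolerance = 1e-12)
  expect_error(spearman_assoc(rep(1, 6), 1:6), "constant")
  expect_error(spearman_assoc(1:3, 1:3), "at least 4")
  # invariance to strictly monotone transforms
  set.seed(3)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(spearman_assoc(x, y)$rho, spearman_assoc(exp(x), rank(y))$rho)
  # p-value agrees with the t-approximation convention
  n <- 4; rho <- 0.6
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  expect_equal(r$p_value, 2 * pt(-abs(tstat), n - 2))
})

test_that("metabolite-wide correlation table is ordered and adjusted", {
  set.seed(8)
  n <- 80
  target <- rnorm(n)
  m <- cbind(hit = exp(0.8 * target + rnorm(n, 0, 0.3)),
             miss = rlnorm(n))
  res <- correlate_metabolites(m, target, target_name = "mrs")
  expect_identical(res$metabolite, c("hit", "miss"))
  expect_gt(res$rho[1], 0.5)
  expect_identical(res$q_value, bh_fdr(res$p_value))
})

test_that("ordination reports non-increasing variance fractions", {
  set.seed(14)
  n <- 30
  axis <- rnorm(n, sd = 4)
  m <- exp(outer(axis, c(1, 1, -1, 0.5)) + matrix(rnorm(n * 4, 0, 0.2), n))
  colnames(m) <- paste0("m", 1:4)
  for (method in c("pca", "pcoa_braycurtis")) {
    ord <- ordinate(m, method = method)
    expect_true(all(ord$var_explained >= 0 & ord$var_explained <= 1))
    expect_true(all(diff(ord$var_explained) <= 0))
    expect_gt(ord$var_explained[1], ord$var_explained[2])
  }
  # identical samples coincide; disjoint compositions are maximally apart
  m2 <- rbind(a = c(5, 0, 1), b = c(5, 0, 1), c = c(0, 7, 0))
  colnames(m2) <- paste0("m", 1:3)
  ord2 <- ordinate(m2, method = "pcoa_braycurtis")
  sc <- as.matrix(ord2$scores[, -1])
  expect_lt(sqrt(sum((sc[1, ] - sc[2, ])^2)), 1e-6)
  expect_gt(sqrt(sum((sc[1, ] - sc[3, ])^2)), 0.5)
  expect_error(ordinate(m2[1:2, ]), "at least 3")
})
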