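cohort_from_2x2 <- function(a, b, c, d) {
  # a: exposed cases, b: exposed controls, c: unexposed cases, d: unexposed
  tibble::tibble(
    exposure = c(rep(1, a + b), rep(0, c + d)),
    nafld = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)))
}

test_that("the adjustment sets are nested as specified", {
  expect_identical(adjustment_covariates("model1"), character(0))
  expect_identical(adjustment_covariates("model2"), c("age", "sex"))
  m3 <- adjustment_covariates("model3")
  expect_true(all(adjustment_covariates("model2") %in% m3))
  expect_setequal(setdiff(m3, adjustment_covariates("model2")),
                  c("marital_status", "education", "income", "smoking",
                    "alcohol", "tea", "energy_intake"))
  expect_identical(setdiff(adjustment_covariates("model4"), m3), "BMI")
})

test_that("crude logistic ORs reproduce 2x2 cross-product ratios", {
  res <- fit_logistic_or(cohort_from_2x2(50, 50, 50, 50), "exposure")
  expect_equal(res$or, 1, tolerance = 1e-6)
  expect_true(res$ci_low < 1 && res$ci_high > 1)

  res4 <- fit_logistic_or(cohort_from_2x2(20, 10, 10, 20), "exposure")
  expect_equal(res4$or, 4, tolerance = 1e-6)

  set.seed(41)
  for (i in 1:30) {
    cells <- sample(5:60, 4, replace = TRUE)
    res_i <- fit_logistic_or(do.call(cohort_from_2x2, as.list(cells)),
                             "exposure")
    expect_equal(res_i$or, (cells[1] * cells[4]) / (cells[2] * cells[3]),
                 tolerance = 1e-6)
  }
})

test_that("per-SD standardisation is the exact affine map", {
  x <- rnorm(50, 10, 3)
  z <- per_sd_standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(per_sd_standardize(mean(x) + 2 * sd(x), reference = x), 2)
  expect_error(per_sd_standardize(rep(3, 5)), "SD is zero")
  # validation-cohort convention: the reference scale is reused unchanged
  y <- rnorm(20, 50, 1)
  expect_equal(per_sd_standardize(y, reference = x),
               (y - mean(x)) / sd(x))
})

test_that("a simulated per-unit effect of ln 2 is estimated near OR 2", {
  set.seed(55)
  x <- rnorm(5000)
  y <- rbinom(5000, 1, plogis(log(2) * x))
  res <- fit_logistic_or(tibble::tibble(exposure = x, nafld = y), "exposure")
  expect_true(res$or > 1.8 && res$or < 2.2)
  expect_true(res$ci_low < 2 && res$ci_high > 2)
})

test_that("an uncorrelated covariate barely moves a large-sample OR", {
  set.seed(66)
  n <- 8000
  d <- tibble::tibble(exposure = rnorm(n), noise = rnorm(n))
  d$nafld <- rbinom(n, 1, plogis(0.6 * d$exposure))
  or0 <- fit_logistic_or(d, "exposure")$or
  or1 <- fit_logistic_or(d, "exposure", adjustment = "noise")$or
  expect_lt(abs(or1 - or0) / or0, 0.02)
})

test_that("separation and collinearity are surfaced explicitly", {
  d <- tibble::tibble(exposure = c(rep(0, 20), rep(1, 20)),
                      nafld = c(rep(0L, 20), rep(1L, 20)))
  expect_error(suppressWarnings(fit_logistic_or(d, "exposure")), "separation")
  set.seed(2)
  d2 <- tibble::tibble(exposure = rnorm(100), age = rnorm(100))
  d2$age_dup <- d2$age
  d2$nafld <- rbinom(100, 1, 0.5)
  expect_warning(fit_logistic_or(d2, "exposure",
                                 adjustment = c("age", "age_dup")),
                 "collinear")
  expect_error(fit_logistic_or(d2, "exposure", adjustment = "ghost"),
               "lacks columns")
})

test_that("quartile ORs use Q1 as the fixed reference", {
  set.seed(10)
  n <- 2000
  q <- factor(sample(paste0("Q", 1:4), n, replace = TRUE),
              levels = paste0("Q", 1:4))
  d <- tibble::tibble(quartile = q, nafld = rbinom(n, 1, 0.4))
  res <- quartile_association(d)
  expect_identical(res$level, paste0("Q", 1:4))
  expect_identical(res$or[1], 1)
  # null association: CIs should rarely exclude 1 across repeated draws
  set.seed(20)
  hits <- replicate(20, {
    qq <- factor(sample(paste0("Q", 1:4), n, replace = TRUE),
                 levels = paste0("Q", 1:4))
    dd <- tibble::tibble(quartile = qq, nafld = rbinom(n, 1, 0.4))
    r <- quartile_association(dd)[-1, ]
    sum(r$ci_low > 1 | r$ci_high < 1)
  })
  expect_lte(mean(hits) / 3, 0.15)
})

test_that("empty quartiles are dropped with a warning", {
  set.seed(30)
  q <- factor(sample(c("Q1", "Q2", "Q4"), 300, replace = TRUE),
              levels = paste0("Q", 1:4))
  d <- tibble::tibble(quartile = q, nafld = rbinom(300, 1, 0.5))
  expect_warning(res <- quartile_association(d), "Q3")
  expect_identical(res$level, c("Q1", "Q2", "Q4"))
})
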