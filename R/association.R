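#' Nested covariate-adjustment sets
#'
#' Four epidemiological adjustment models: model 1 is crude; model 2 adds age
#' and sex; model 3 adds marital status, education, income, smoking, alcohol,
#' tea drinking and total energy intake; model 4 additionally adjusts for BMI.
#'
#' @param model One of `"model1"`..`"model4"`.
#' @return Character vector of covariate names (empty for `"model1"`).
#' @export
adjustment_covariates <- function(model = c("model1", "model2", "model3",
                                            "model4")) {
  model <- match.arg(model)
  m2 <- c("age", "sex")
  m3 <- c(m2, "marital_status", "education", "income", "smoking", "alcohol",
          "tea", "energy_intake")
  switch(model, model1 = character(0), model2 = m2, model3 = m3,
         model4 = c(m3, "BMI"))
}

# covariates dummy-coded with first level as reference
categorical_covariates <- function() {
  c("sex", "marital_status", "education", "income", "smoking", "alcohol",
    "tea")
}

#' Standardise to a reference cohort's scale
#'
#' Centres and scales by the reference mean and SD, so odds ratios for the
#' resulting z-scores are per-1-SD effects. For validation cohorts, pass the
#' discovery cohort's values as `reference` so its SD is reused unchanged.
#'
#' @param values Numeric vector to standardise.
#' @param reference Numeric vector defining mean and SD (defaults to
#'   `values`).
#' @return Numeric z-score vector.
#' @export
per_sd_standardize <- function(values, reference = values) {
  s <- sd(reference)
  if (!is.finite(s) || s == 0) abort("reference SD is zero; cannot standardise")
  (values - mean(reference)) / s
}

#' Logistic odds ratio for one exposure under an adjustment model
#'
#' Maximum-likelihood logistic regression of the binary outcome on the
#' exposure plus the adjustment covariates; Wald 95% confidence interval on
#' the exposure coefficient, exponentiated to the OR scale. Categorical
#' covariates are dummy-coded with the first level as reference; individuals
#' with a missing outcome, exposure or covariate are dropped complete-case.
#'
#' @param data Tibble containing the outcome column, the exposure column and
#'   all adjustment covariates.
#' @param exposure Name of the exposure column (numeric, or a factor for
#'   categorical exposures such as score quartiles).
#' @param adjustment `"model1"`..`"model4"`, or a character vector of
#'   covariate names.
#' @param outcome Name of the 0/1 outcome column.
#' @param per_sd If `TRUE`, standardise a numeric exposure with
#'   [per_sd_standardize()] before fitting (using `reference` for the scale).
#' @param reference Reference values for `per_sd` (defaults to the exposure
#'   column of `data`).
#' @param conf_level Confidence level for the Wald interval.
#' @return A tibble of class `mrs_association`: `exposure`, `level`, `model`,
#'   `or`, `ci_low`, `ci_high`, `p_value`, `n` (one row per non-reference
#'   exposure level).
#' @export
fit_logistic_or <- function(data, exposure, adjustment = "model1",
                            outcome = "nafld", per_sd = FALSE,
                            reference = NULL, conf_level = 0.95) {
  covs <- if (length(adjustment) == 1 &&
              adjustment %in% paste0("model", 1:4)) {
    adjustment_covariates(adjustment)
  } else {
    as.character(adjustment)
  }
  model_label <- if (length(adjustment) == 1 &&
                     adjustment %in% paste0("model", 1:4)) adjustment else
                       "custom"
  need <- c(outcome, exposure, covs)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("data lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(data)[, need, drop = FALSE]
  n0 <- nrow(df)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < n0) {
    inform(paste0("dropped ", n0 - nrow(df), " incomplete cases"))
  }
  if (!all(df[[outcome]] %in% c(0, 1))) abort("outcome must be binary 0/1")
  for (v in intersect(covs, categorical_covariates())) {
    df[[v]] <- factor(df[[v]])
    if (nlevels(df[[v]]) < 2) df[[v]] <- NULL
  }
  covs <- intersect(covs, names(df))
  if (per_sd) {
    if (!is.numeric(df[[exposure]])) abort("per_sd requires a numeric exposure")
    ref <- reference %||% df[[exposure]]
    df[[exposure]] <- per_sd_standardize(df[[exposure]], ref)
  }
  fml <- as.formula(paste(outcome, "~",
                          paste(c(sprintf("`%s`", exposure),
                                  sprintf("`%s`", covs)), collapse = " + ")))
  fit <- glm(fml, data = df, family = binomial())
  cf <- coef(fit)
  if (anyNA(cf)) {
    dropped <- names(cf)[is.na(cf)]
    warn(paste0("collinear terms dropped: ", paste(dropped, collapse = ", ")))
  }
  keep <- grep(paste0("^`?", exposure, "`?"), names(cf), value = TRUE)
  est <- cf[keep]
  if (anyNA(est) || any(abs(est) > 20)) {
    abort(paste0("separation or non-identifiability detected for exposure ",
                 exposure, " (|log OR| > 20); the odds ratio is not estimable"))
  }
  se <- sqrt(diag(vcov(fit))[keep])
  z <- qnorm(1 - (1 - conf_level) / 2)
  lev <- sub(paste0("^`?", exposure, "`?"), "", keep)
  out <- tibble(
    exposure = exposure,
    level = ifelse(lev == "", NA_character_, lev),
    model = model_label,
    or = exp(unname(est)),
    ci_low = exp(unname(est - z * se)),
    ci_high = exp(unname(est + z * se)),
    p_value = 2 * pnorm(-abs(unname(est) / se)),
    n = nrow(df))
  class(out) <- c("mrs_association", class(out))
  out
}

#' Quartile odds ratios with the lowest quartile as reference
#'
#' Indicator-coded logistic regression of the outcome on score quartiles
#' under an adjustment model. Q1 is the reference (OR fixed at 1 by
#' construction); empty quartiles are dropped with a warning.
#'
#' @param data Tibble containing the outcome, a `quartile` factor (from
#'   [quartile_bins()]) and the adjustment covariates.
#' @inheritParams fit_logistic_or
#' @return An `mrs_association` tibble with one row per quartile, including
#'   the Q1 reference row.
#' @export
quartile_association <- function(data, adjustment = "model1",
                                 outcome = "nafld", conf_level = 0.95) {
  if (!"quartile" %in% names(data)) {
    abort("data needs a quartile column; see quartile_bins()")
  }
  q <- data$quartile
  if (!is.factor(q)) q <- factor(q)
  empty <- setdiff(levels(q), unique(as.character(q)))
  if (length(empty) > 0) {
    warn(paste0("empty quartiles dropped: ", paste(empty, collapse = ", ")))
    q <- droplevels(q)
  }
  if (nlevels(q) < 2) abort("need at least two non-empty quartiles")
  d <- mutate(data, quartile = q)
  fit <- fit_logistic_or(d, "quartile", adjustment = adjustment,
                         outcome = outcome, conf_level = conf_level)
  ref <- tibble(exposure = "quartile", level = levels(q)[1],
                model = fit$model[1], or = 1, ci_low = 1, ci_high = 1,
                p_value = NA_real_, n = fit$n[1])
  out <- bind_rows(ref, fit)
  class(out) <- c("mrs_association", class(out))
  out
}
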