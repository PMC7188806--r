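#' One-sample and paired t-tests with effect sizes
#'
#' Thin wrappers around [stats::t.test()] returning a flat list suitable for
#' row-binding into group tables: mean, SEM, df, t, two-sided p, and Cohen's
#' d (mean / SD; for the paired test, of the differences). Inputs whose SD is
#' zero (or with n < 2) are flagged instead of tested.
#'
#' @param x Numeric vector (per-subject estimates, or condition A).
#' @param mu0 Null value for the one-sample test.
#' @return Named list: `mean`, `sem`, `df`, `statistic`, `p_value`,
#'   `cohens_d`, `flagged`.
#' @export
one_sample_t <- function(x, mu0 = 0) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2 || sd(x) == 0) {
    return(list(mean = if (n) mean(x) else NA_real_,
                sem = NA_real_, df = NA_real_, statistic = NA_real_,
                p_value = NA_real_, cohens_d = NA_real_, flagged = TRUE))
  }
  tt <- t.test(x, mu = mu0)
  list(mean = mean(x), sem = sd(x) / sqrt(n),
       df = unname(tt$parameter), statistic = unname(tt$statistic),
       p_value = tt$p.value, cohens_d = (mean(x) - mu0) / sd(x),
       flagged = FALSE)
}

#' @param y Condition B, aligned with `x`.
#' @rdname one_sample_t
#' @export
paired_t <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  one_sample_t(x[ok] - y[ok])
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment (wraps
#' `p.adjust(method = "BH")`): monotone after sorting and capped at 1.
#'
#' @param p Vector of p-values.
#' @return Adjusted q-values in the original order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.04, 0.5))
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    abort("p-values must lie in [0, 1]", class = "ctdlearn_domain_error")
  }
  p.adjust(p, method = "BH")
}

#' Ordinary least squares / logistic fits as regression results
#'
#' Convenience wrappers used by the higher-level analyses: `ols_fit` runs
#' [stats::lm()], `logistic_fit` runs [stats::glm()] with a logistic link
#' (flagging non-convergence and likely separation).
#'
#' @param outcome Numeric outcome (0/1 for `logistic_fit`).
#' @param predictors Data frame or named matrix of predictors; an intercept
#'   is always added.
#' @param model Model tag stored in the result.
#' @return A `regression_result`.
#' @export
ols_fit <- function(outcome, predictors, model = "ols") {
  df <- data.frame(.y = outcome, predictors, check.names = FALSE)
  x <- stats::model.matrix(.y ~ ., df)
  if (qr(x)$rank < ncol(x)) {
    abort("rank-deficient predictor matrix", class = "ctdlearn_domain_error")
  }
  new_regression_result(lm(.y ~ ., data = df), model, nrow(df))
}

#' @rdname ols_fit
#' @export
logistic_fit <- function(outcome, predictors, model = "logistic") {
  df <- data.frame(.y = outcome, predictors, check.names = FALSE)
  fit <- suppressWarnings(glm(.y ~ ., family = binomial(), data = df))
  sep <- any(abs(coef(fit)) > 15) || any(summary(fit)$coefficients[, 2] > 100)
  new_regression_result(fit, model, nrow(df),
                        converged = fit$converged,
                        flagged = !fit$converged || sep,
                        note = if (!fit$converged) "non-convergence"
                               else if (sep) "possible separation")
}
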