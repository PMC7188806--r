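new_regression_result <- function(fit, model, n, converged = TRUE,
                                  flagged = FALSE, note = NULL) {
  sm <- summary(fit)
  co <- if (inherits(fit, "glm")) sm$coefficients else sm$coefficients
  structure(list(
    coefficients = tibble::tibble(
      term = rownames(co),
      estimate = unname(co[, 1]),
      std_error = unname(co[, 2]),
      statistic = unname(co[, 3]),
      p_value = unname(co[, 4])),
    model = model, n = n,
    sigma = if (!inherits(fit, "glm")) sm$sigma else NA_real_,
    converged = converged, flagged = flagged, note = note),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %s, n = %d%s\n", x$model, x$n,
              if (x$flagged) sprintf(" [flagged: %s]", x$note) else ""))
  print(x$coefficients)
  invisible(x)
}

#' @method tidy regression_result
#' @export
tidy.regression_result <- function(x, ...) x$coefficients

#' @method glance regression_result
#' @export
glance.regression_result <- function(x, ...) {
  tibble::tibble(model = x$model, n = x$n, sigma = x$sigma,
                 converged = x$converged, flagged = x$flagged)
}

prepare_model_frame <- function(behavior) {
  incl <- behavior$included %||% rep(TRUE, nrow(behavior))
  df <- behavior[incl, , drop = FALSE]
  if (nrow(df) < 4) abort("fewer included trials than regressors",
                          class = "ctdlearn_domain_error")
  df$pe_temporal_z <- zscore(df$pe_temporal, "pe_temporal")
  df$pe_contextual_z <- zscore(df$pe_contextual, "pe_contextual")
  df
}

#' Logistic regression of accuracy on model prediction errors
#'
#' Per-subject maximum-likelihood logistic regression of trial accuracy on
#' the z-scored temporal and contextual prediction errors, with the task cue
#' (0 = face, 1 = object) and a constant as covariates. Accuracy models use
#' all trials (error trials are the outcome, not an exclusion); only the RT
#' filters' `included` flag is ignored here unless `use_included` is set.
#'
#' Fits that fail to converge or show signs of separation are returned with
#' `flagged = TRUE` so the group stage can drop them with a warning.
#'
#' @param behavior Trial tibble with `accuracy`, `pe_temporal`,
#'   `pe_contextual`, `task`.
#' @param use_included Honor an `included` column if present (default
#'   `FALSE`).
#' @return A `regression_result` (model tag `"logistic_accuracy"`).
#' @export
fit_accuracy_model <- function(behavior, use_included = FALSE) {
  df <- behavior
  if (use_included && "included" %in% names(df)) df <- df[df$included, ]
  df$pe_temporal_z <- zscore(df$pe_temporal, "pe_temporal")
  df$pe_contextual_z <- zscore(df$pe_contextual, "pe_contextual")
  fit <- suppressWarnings(
    glm(accuracy ~ pe_temporal_z + pe_contextual_z + task,
        family = binomial(), data = df))
  sep <- any(abs(coef(fit)) > 15) ||
    any(summary(fit)$coefficients[, 2] > 100)
  new_regression_result(fit, "logistic_accuracy", nrow(df),
                        converged = fit$converged,
                        flagged = !fit$converged || sep,
                        note = if (!fit$converged) "non-convergence"
                               else if (sep) "possible separation")
}

#' Linear regression of log-RT on model prediction errors
#'
#' Per-subject ordinary least squares of natural-log RT on the z-scored
#' temporal and contextual prediction errors, task cue and constant, over the
#' trials retained by [filter_trials()].
#'
#' @param behavior Output of [filter_trials()] (or any trial tibble with an
#'   `included` column plus `log_rt`, `pe_temporal`, `pe_contextual`,
#'   `task`).
#' @param extra Optional character vector of additional covariate columns.
#' @return A `regression_result` (model tag `"ols_logrt"`).
#' @export
fit_rt_model <- function(behavior, extra = NULL) {
  df <- prepare_model_frame(behavior)
  rhs <- c("pe_temporal_z", "pe_contextual_z", "task", extra)
  f <- as.formula(paste("log_rt ~", paste(rhs, collapse = " + ")))
  x <- stats::model.matrix(f, df)
  if (qr(x)$rank < ncol(x)) {
    abort("RT design matrix is rank deficient", class = "ctdlearn_domain_error")
  }
  new_regression_result(lm(f, data = df), "ols_logrt", nrow(df))
}

#' Quintile summary of an outcome against a prediction error
#'
#' Per subject, included trials are ranked by the prediction error and split
#' into five equal-count bins (any remainder goes to the lowest bins); the
#' group mean and SEM of the outcome per bin are returned. With a single
#' subject the SEM is across that subject's trials within each bin.
#'
#' @param behavior Trial tibble; rows with `included == FALSE` are dropped.
#' @param outcome,pe Column names of the outcome and the ranking variable.
#' @param subject Optional subject-id column for group summaries.
#' @return Tibble with `bin`, `mean`, `sem` and `n` (class
#'   `ctd_quintiles`).
#' @export
quintile_summary <- function(behavior, outcome, pe, subject = NULL) {
  df <- if ("included" %in% names(behavior)) {
    behavior[behavior$included, ]
  } else behavior
  assign_bins <- function(n) {
    if (n < 5) abort("need at least 5 trials for a quintile split",
                     class = "ctdlearn_domain_error")
    sizes <- n %/% 5 + as.integer(seq_len(5) <= n %% 5)
    rep(seq_len(5), sizes)
  }
  per_subject <- function(d) {
    ord <- order(d[[pe]])
    tibble::tibble(bin = assign_bins(nrow(d)),
                   value = d[[outcome]][ord]) |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  }
  out <- if (is.null(subject)) {
    ord <- order(df[[pe]])
    tibble::tibble(bin = assign_bins(nrow(df)),
                   value = df[[outcome]][ord]) |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(mean = mean(.data$value),
                       sem = sd(.data$value) / sqrt(dplyr::n()),
                       n = dplyr::n(), .groups = "drop")
  } else {
    df |>
      dplyr::group_by(.subj = .data[[subject]]) |>
      dplyr::group_modify(~per_subject(.x)) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(mean = mean(.data$value),
                       sem = sd(.data$value) / sqrt(dplyr::n()),
                       n = dplyr::n(), .groups = "drop")
  }
  class(out) <- c("ctd_quintiles", class(out))
  attr(out, "outcome") <- outcome
  attr(out, "pe") <- pe
  out
}

#' Group-level inference over per-subject coefficients
#'
#' Two-stage (subject-then-group) inference: for every term, a two-sided
#' one-sample t-test of the per-subject coefficients against zero, Cohen's d
#' (mean / SD of the coefficients), and Benjamini-Hochberg adjusted q-values
#' within the family of terms passed in. Terms with zero variance across
#' subjects are flagged rather than tested.
#'
#' @param coefs Tibble with columns `subject`, `term`, `estimate` (e.g.
#'   per-subject [tidy()] outputs bound together). Rows from flagged subject
#'   fits should be removed before calling (see `drop_subjects`).
#' @param drop_subjects Optional subject ids to exclude (e.g. flagged
#'   logistic fits); a warning reports how many were dropped.
#' @return Tibble (class `ctd_group_stats`): `term`, `mean`, `sem`, `df`,
#'   `statistic`, `p_value`, `cohens_d`, `q_value`, `flagged`.
#' @export
group_inference <- function(coefs, drop_subjects = NULL) {
  if (!is.null(drop_subjects) && length(drop_subjects)) {
    warn(sprintf("dropping %d flagged subject(s) from group inference",
                 length(unique(drop_subjects))))
    coefs <- coefs[!coefs$subject %in% drop_subjects, ]
  }
  out <- coefs |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(res = list(one_sample_t(.data$estimate)),
                     .groups = "drop") |>
    tidyr::unnest_wider("res")
  out$q_value <- NA_real_
  ok <- !out$flagged
  out$q_value[ok] <- bh_fdr(out$p_value[ok])
  class(out) <- c("ctd_group_stats", class(out))
  out
}
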