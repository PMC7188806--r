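#' Per-event univariate activity as a tidy table
#'
#' @param ps A `pattern_set`.
#' @return Tibble with `event_id`, `class`, `block_id`, `trial_id`, `run`
#'   and `univariate` (ROI-mean amplitude).
#' @export
event_univariate <- function(ps) {
  tibble::tibble(event_id = ps$events$event_id, class = ps$events$class,
                 block_id = ps$events$block_id,
                 trial_id = ps$events$trial_id, run = ps$events$run,
                 univariate = roi_univariate(ps))
}

#' Trial-level regression of RT on CTD reinstatement
#'
#' Per-subject OLS of log-RT on the trial-level reinstatement score, with
#' temporal-model prediction error, task and trial-level ROI-mean univariate
#' activity as covariates of no interest (optionally adding the contextual
#' prediction error). Only trials retained by the behavioral filters and
#' holding a reinstatement score enter the fit. Negative reinstatement
#' coefficients mean stronger reinstatement, faster responses.
#'
#' @param behavior Output of [filter_trials()].
#' @param reinst Output of [trial_reinstatement()].
#' @param univariate Optional tibble from [event_univariate()] (its
#'   `trial_cue` rows supply the per-trial covariate).
#' @param add_contextual Also include the contextual PE as a covariate.
#' @return A `regression_result` (model tag `"trial_rt_reinstatement"`).
#' @export
trial_rt_regression <- function(behavior, reinst, univariate = NULL,
                                add_contextual = FALSE) {
  df <- prepare_model_frame(behavior)
  df <- dplyr::inner_join(df, reinst, by = "trial_id")
  if (!is.null(univariate)) {
    uv <- univariate[univariate$class == "trial_cue",
                     c("trial_id", "univariate")]
    df <- dplyr::inner_join(df, uv, by = "trial_id")
  } else {
    df$univariate <- 0
  }
  if (nrow(df) < 6) abort("too few trials with reinstatement scores",
                          class = "ctdlearn_domain_error")
  rhs <- c("reinstatement", "pe_temporal_z",
           if (add_contextual) "pe_contextual_z", "task",
           if (sd(df$univariate) > 0) "univariate")
  f <- as.formula(paste("log_rt ~", paste(rhs, collapse = " + ")))
  x <- stats::model.matrix(f, df)
  if (qr(x)$rank < ncol(x)) {
    abort("rank-deficient design in trial RT regression",
          class = "ctdlearn_domain_error")
  }
  new_regression_result(lm(f, data = df), "trial_rt_reinstatement", nrow(df))
}

#' Block-level context-context similarity per condition
#'
#' For each block, the mean Fisher z of that block's context-onset pattern
#' against all eligible cross-run context-onset patterns, split by context
#' relation — a block-resolved view of pattern separation, so it can be
#' related to that block's reinstatement and behavior.
#'
#' @param cc Output of [context_context_similarity()].
#' @return Tibble with `block_id` and one column per relation
#'   (`same_context`, `same_ctd`, `different_ctd`).
#' @export
block_level_similarity <- function(cc) {
  block <- c(cc$block_a, cc$block_b)
  rel <- c(cc$relation, cc$relation)
  z <- c(cc$z, cc$z)
  out <- tibble::tibble(block_id = sort(unique(block)))
  for (r in relation_levels) {
    sel <- rel == r
    f <- factor(block[sel], levels = out$block_id)
    n <- tabulate(f, nbins = nrow(out))
    s <- numeric(nrow(out))
    agg <- rowsum(z[sel], f)
    s[match(rownames(agg), as.character(out$block_id))] <- agg[, 1]
    out[[r]] <- ifelse(n > 0, s / n, NA_real_)
  }
  out
}

#' Hippocampal-cortical coupling regression over blocks
#'
#' Per-subject OLS of block-wise cortical CTD reinstatement on four
#' hippocampal predictors — context-context similarity in the Same Context,
#' Same CTD and Different CTD conditions, plus univariate activity — with
#' the cortical ROI's univariate activity as a covariate of no interest.
#' Predictors and covariates are z-scored across blocks within subject so
#' group-level coefficients are comparable.
#'
#' @param blocks Tibble with one row per retained block containing the
#'   outcome and predictor columns.
#' @param outcome Outcome column (block-wise reinstatement).
#' @param predictors Predictor columns (the four hippocampal measures).
#' @param covariates Covariate columns (cortical univariate activity);
#'   missing columns are skipped.
#' @return A `regression_result` (model tag `"block_coupling"`).
#' @export
block_coupling_regression <- function(blocks, outcome = "reinstatement",
                                      predictors = c("h_same_context",
                                                     "h_same_ctd",
                                                     "h_different_ctd",
                                                     "h_univariate"),
                                      covariates = "cortical_univariate") {
  covariates <- intersect(covariates, names(blocks))
  df <- blocks[stats::complete.cases(blocks[c(outcome, predictors,
                                              covariates)]), ]
  if (nrow(df) < length(predictors) + length(covariates) + 2) {
    abort("too few blocks for the coupling regression",
          class = "ctdlearn_domain_error")
  }
  for (v in c(predictors, covariates)) df[[v]] <- zscore(df[[v]], v)
  f <- as.formula(paste(outcome, "~",
                        paste(c(predictors, covariates), collapse = " + ")))
  new_regression_result(lm(f, data = df), "block_coupling", nrow(df))
}

#' Trial-level RT regression on congruency-signed hippocampal measures
#'
#' Broadcasts the block-level hippocampal predictors (univariate activity
#' and the three context-context similarity conditions) to the block's
#' trials, applies the trial's match/mismatch factor (+1 congruent, -1
#' incongruent), and regresses log-RT on the signed predictors with the
#' standard covariates (temporal PE, task). Designs in which the congruency
#' factor is constant are fitted but flagged.
#'
#' @param behavior Output of [filter_trials()] (needs `block_id`,
#'   `congruent`).
#' @param blocks Tibble with `block_id` and hippocampal predictor columns.
#' @param predictors Hippocampal predictor columns in `blocks`.
#' @param extra Additional trial-level covariate columns in `behavior`
#'   (e.g. a broadcast cortical reinstatement).
#' @return A `regression_result` (model tag `"hippo_rt"`).
#' @export
hippo_rt_regression <- function(behavior, blocks,
                                predictors = c("h_univariate",
                                               "h_same_context",
                                               "h_same_ctd",
                                               "h_different_ctd"),
                                extra = NULL) {
  df <- prepare_model_frame(behavior)
  df <- dplyr::inner_join(df, blocks[c("block_id", predictors)],
                          by = "block_id")
  df <- df[stats::complete.cases(df[predictors]), ]
  sign <- ifelse(df$congruent, 1, -1)
  for (v in predictors) df[[v]] <- sign * zscore(df[[v]], v)
  rhs <- c(predictors, "pe_temporal_z", "task", extra)
  f <- as.formula(paste("log_rt ~", paste(rhs, collapse = " + ")))
  fit <- lm(f, data = df)
  degenerate <- length(unique(sign)) == 1L
  new_regression_result(fit, "hippo_rt", nrow(df),
                        flagged = degenerate,
                        note = if (degenerate) "congruency factor constant")
}

#' Across-subject correlation of neural similarity and behavior
#'
#' Pearson correlation, across subjects, between a per-subject neural
#' summary (e.g. mean hippocampal Same-CTD context-context similarity) and a
#' per-subject behavioral summary (e.g. the contextual-PE modulation of
#' accuracy), with a two-sided p-value.
#'
#' @param neural,behavioral Aligned per-subject numeric vectors (n >= 3).
#' @return Tibble with `r`, `statistic`, `df`, `p_value`, `n`.
#' @export
cross_subject_correlation <- function(neural, behavioral) {
  ok <- is.finite(neural) & is.finite(behavioral)
  if (sum(ok) < 3) abort("need at least 3 subjects for a correlation",
                         class = "ctdlearn_domain_error")
  ct <- cor.test(neural[ok], behavioral[ok])
  tibble::tibble(r = unname(ct$estimate), statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 n = sum(ok))
}
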