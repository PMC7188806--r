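#' Generative parameters for synthetic behavior
#'
#' Planted-truth container for the forward model of trial-level behavior.
#' Log-RT is composed as
#' `rt_intercept + rt_pe_temporal * PE_t + rt_pe_contextual * PE_c +
#'  rt_task * task + rt_reinstatement * R + noise`,
#' where the prediction errors come from the delta-rule learners run at the
#' true learning rates and, by default, are z-scored within subject so the
#' planted coefficients live on the same scale as the fitted ones. Accuracy
#' is drawn from a logistic model in the same predictors.
#'
#' Defaults place the coefficients in the range reported for this paradigm:
#' overall RT near 1100 ms with objects ~60 ms slower than faces, a positive
#' temporal-PE effect of 0.03 on log-RT, a smaller positive contextual-PE
#' effect of 0.01, and a contextual-PE accuracy coefficient of -0.19 on the
#' logit scale (larger contextual surprise, more errors).
#'
#' @param alpha_temporal,alpha_contextual True learning rates in (0, 1).
#' @param rt_intercept Mean log-RT (log milliseconds).
#' @param rt_pe_temporal,rt_pe_contextual,rt_task,rt_reinstatement
#'   Coefficients on the log-RT scale.
#' @param rt_noise_sd Gaussian noise SD on log-RT; must be positive.
#' @param acc_intercept,acc_pe_temporal,acc_pe_contextual,acc_task
#'   Logistic-regression coefficients for accuracy (logit scale).
#' @param pe_scale `"z"` (default) to z-score the PE regressors within
#'   subject before composing behavior, `"raw"` to use them untransformed.
#' @return An object of class `generative_params`.
#' @export
generative_params <- function(alpha_temporal = 0.30,
                              alpha_contextual = 0.10,
                              rt_intercept = log(1100),
                              rt_pe_temporal = 0.03,
                              rt_pe_contextual = 0.01,
                              rt_task = 0.057,
                              rt_reinstatement = -0.06,
                              rt_noise_sd = 0.20,
                              acc_intercept = 2.2,
                              acc_pe_temporal = 0.09,
                              acc_pe_contextual = -0.19,
                              acc_task = 0,
                              pe_scale = c("z", "raw")) {
  stopifnot_scalar_prob(alpha_temporal, "alpha_temporal", open = TRUE)
  stopifnot_scalar_prob(alpha_contextual, "alpha_contextual", open = TRUE)
  if (!is.numeric(rt_noise_sd) || rt_noise_sd < 0) {
    abort("`rt_noise_sd` must be >= 0", class = "ctdlearn_config_error")
  }
  structure(list(alpha_temporal = alpha_temporal,
                 alpha_contextual = alpha_contextual,
                 rt_intercept = rt_intercept,
                 rt_pe_temporal = rt_pe_temporal,
                 rt_pe_contextual = rt_pe_contextual,
                 rt_task = rt_task,
                 rt_reinstatement = rt_reinstatement,
                 rt_noise_sd = rt_noise_sd,
                 acc_intercept = acc_intercept,
                 acc_pe_temporal = acc_pe_temporal,
                 acc_pe_contextual = acc_pe_contextual,
                 acc_task = acc_task,
                 pe_scale = match.arg(pe_scale)),
            class = "generative_params")
}

#' Simulate trial-level behavior from the delta-rule forward model
#'
#' Runs the temporal and contextual learners at the true learning rates over
#' the design's trial sequence, then draws accuracy (logistic link) and
#' log-RT (Gaussian noise) from the planted linear models. Post-error flags
#' mark trials immediately following an error within the same run.
#'
#' @param design A `session_design`.
#' @param params A [generative_params()] object.
#' @param seed Integer seed.
#' @param reinstatement Optional per-trial reinstatement predictor (e.g. the
#'   signed block gain from the neural simulator); z-scored before entering
#'   the RT model when it has nonzero variance.
#' @return The design's `trials` tibble with added columns `pe_temporal`,
#'   `pe_contextual` (raw PEs at the true rates), `accuracy`, `post_error`,
#'   `rt_ms` and `log_rt`.
#' @export
#' @examples
#' d <- generate_design(design_spec(), seed = 1)
#' b <- generate_behavior(d, generative_params(), seed = 1)
#' mean(b$accuracy)
generate_behavior <- function(design, params = generative_params(), seed = 1,
                              reinstatement = NULL) {
  tr <- design$trials
  pe_t <- run_temporal_model(tr$task, params$alpha_temporal)$pe
  pe_c <- run_contextual_model(tr$task, tr$context,
                               params$alpha_contextual)$pe
  xt <- if (params$pe_scale == "z") zscore_(pe_t) else pe_t
  xc <- if (params$pe_scale == "z") zscore_(pe_c) else pe_c
  r <- reinstatement %||% rep(0, nrow(tr))
  if (length(r) != nrow(tr)) {
    abort("`reinstatement` must have one value per trial",
          class = "ctdlearn_domain_error")
  }
  if (sd(r) > 0) r <- zscore_(r)

  with_seed(seed, {
    eta <- params$acc_intercept + params$acc_pe_temporal * xt +
      params$acc_pe_contextual * xc + params$acc_task * tr$task
    accuracy <- rbinom(nrow(tr), 1, stats::plogis(eta))
    mu <- params$rt_intercept + params$rt_pe_temporal * xt +
      params$rt_pe_contextual * xc + params$rt_task * tr$task +
      params$rt_reinstatement * r
    log_rt <- mu + rnorm(nrow(tr), sd = params$rt_noise_sd)
  })

  prev_err <- dplyr::lag(accuracy == 0, default = FALSE)
  same_run <- dplyr::lag(tr$run, default = tr$run[1]) == tr$run
  tr$pe_temporal <- pe_t
  tr$pe_contextual <- pe_c
  tr$accuracy <- accuracy
  tr$post_error <- prev_err & same_run
  tr$log_rt <- log_rt
  tr$rt_ms <- exp(log_rt)
  tr
}
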