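#' Pipeline configuration
#'
#' Bundles the design, generative and neural parameters with the analysis
#' switches. Unknown fields are rejected. The defaults reproduce the
#' standard synthetic study: 33 subjects, 6 runs, planted behavioral and
#' neural effects, full 99-point learning-rate grid.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param design A [design_spec()].
#' @param gen A [generative_params()].
#' @param neural A [neural_params()].
#' @param fit_alphas Fit learning rates by grid search (`TRUE`) or analyze
#'   at the true generative rates (`FALSE`, much faster; used by the
#'   calibration harness).
#' @param grid Learning-rate lattice for the grid search.
#' @param rho_subject_sd Across-subject SD of the hippocampal same-CTD
#'   correlation offset (subject heterogeneity).
#' @param xs_coupling Coupling from a subject's same-CTD correlation offset
#'   to their contextual-PE accuracy coefficient (plants the across-subject
#'   similarity-behavior correlation).
#' @param similarity_runs Runs used for the reinstatement (context-trial)
#'   analyses; `NULL` means all runs except run 1.
#' @param seed Master seed; per-subject streams are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 33,
                            design = design_spec(),
                            gen = generative_params(),
                            neural = neural_params(),
                            fit_alphas = TRUE,
                            grid = seq(0.01, 0.99, by = 0.01),
                            rho_subject_sd = 0.1,
                            xs_coupling = 4,
                            similarity_runs = NULL,
                            seed = 1) {
  stopifnot(inherits(design, "design_spec"),
            inherits(gen, "generative_params"),
            inherits(neural, "neural_params"),
            is.numeric(n_subjects), n_subjects >= 1)
  structure(list(n_subjects = as.integer(n_subjects), design = design,
                 gen = gen, neural = neural, fit_alphas = fit_alphas,
                 grid = grid, rho_subject_sd = rho_subject_sd,
                 xs_coupling = xs_coupling,
                 similarity_runs = similarity_runs, seed = seed),
            class = "pipeline_config")
}

#' Null counterpart of a configuration
#'
#' Returns a copy of `config` with every planted effect removed: zero PE and
#' reinstatement coefficients on behavior, zero reinstatement gain and
#' hippocampal-cortical couplings, equal same-CTD and different-CTD
#' correlation targets, and no across-subject coupling. Used to check that
#' every group test is calibrated at its nominal level.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_config` with all effects nulled.
#' @export
as_null_config <- function(config) {
  g <- config$gen
  g$rt_pe_temporal <- g$rt_pe_contextual <- g$rt_reinstatement <- 0
  g$acc_pe_temporal <- g$acc_pe_contextual <- 0
  n <- config$neural
  n$gain_mean <- n$gain_hippo_fluct <- n$gain_hippo_amp <- 0
  n$rho_hippo_same_ctd <- n$rho_hippo_diff_ctd
  config$gen <- g
  config$neural <- n
  config$rho_subject_sd <- 0
  config$xs_coupling <- 0
  config
}

#' Simulate one subject's session
#'
#' Generates the design, the block-level latent neural states, behavior
#' whose RT carries the congruency-signed block reinstatement gain, and the
#' multi-voxel patterns sharing those same block states — so every effect a
#' downstream analysis tests has a single planted source.
#'
#' @param design_spec A [design_spec()].
#' @param gen A [generative_params()].
#' @param neural A [neural_params()].
#' @param seed Subject-level seed.
#' @return List with `design`, `behavior`, `patterns`, `block_states`.
#' @export
simulate_subject <- function(design_spec = design_spec(),
                             gen = generative_params(),
                             neural = neural_params(), seed = 1) {
  design <- generate_design(design_spec, derive_seed(seed, 1))
  states <- draw_block_states(design, neural, derive_seed(seed, 2))
  gain_tr <- states$gain[match(design$trials$block_id, states$block_id)]
  signed_gain <- ifelse(design$trials$congruent, 1, -1) * gain_tr
  behavior <- generate_behavior(design, gen, derive_seed(seed, 3),
                                reinstatement = signed_gain)
  patterns <- generate_patterns(design, neural, derive_seed(seed, 4),
                                block_states = states)
  list(design = design, behavior = behavior, patterns = patterns,
       block_states = states)
}

# Recompute PE columns at given learning rates.
set_pe_columns <- function(behavior, alpha_t, alpha_c) {
  behavior$pe_temporal <- run_temporal_model(behavior$task, alpha_t)$pe
  behavior$pe_contextual <- run_contextual_model(behavior$task,
                                                 behavior$context,
                                                 alpha_c)$pe
  behavior
}

#' Analyze one subject's session
#'
#' Runs the full per-subject analysis chain: trial filtering, (optionally)
#' grid-search learning-rate fitting, accuracy and RT regressions on the
#' fitted prediction errors, cortical context-trial similarity with the
#' factorial reinstatement measures, hippocampal context-context similarity
#' with block-level separation measures, the trial-level
#' reinstatement-to-RT regression, the block-level coupling regression and
#' the congruency-signed hippocampal RT regression.
#'
#' @param sub Output of [simulate_subject()] (or a compatible list).
#' @param fit_alphas Fit learning rates by grid search; otherwise analyze at
#'   the supplied `alphas`.
#' @param grid Grid for the search.
#' @param alphas Fallback learning rates `c(temporal, contextual)` when
#'   `fit_alphas = FALSE`.
#' @param similarity_runs Runs for the context-trial analyses (`NULL`: all
#'   but run 1).
#' @return Named list of per-subject results.
#' @export
analyze_subject <- function(sub, fit_alphas = TRUE,
                            grid = seq(0.01, 0.99, by = 0.01),
                            alphas = NULL, similarity_runs = NULL) {
  behavior <- filter_trials(sub$behavior)
  if (fit_alphas) {
    gs <- grid_search_alphas(behavior, grid = grid)
    alphas <- c(gs$alpha_temporal, gs$alpha_contextual)
  } else {
    gs <- NULL
    if (is.null(alphas) || length(alphas) != 2) {
      abort("`alphas` (temporal, contextual) must be supplied when `fit_alphas = FALSE`",
            class = "ctdlearn_domain_error")
    }
  }
  behavior <- set_pe_columns(behavior, alphas[1], alphas[2])
  rt_fit <- fit_rt_model(behavior)
  acc_fit <- fit_accuracy_model(behavior)

  included_ids <- behavior$trial_id[behavior$included]
  ct_ps <- exclude_events(sub$patterns$cortical,
                          include_trial_ids = included_ids,
                          drop_run1 = TRUE)
  sim <- context_trial_similarity(ct_ps, runs = similarity_runs)
  cells <- cell_means(sim)
  contrast <- reinstatement_contrast(cells)
  congr <- c(same_pooled = congruency_effect(cells, "same_pooled"),
             same_ctd = congruency_effect(cells, "same_ctd"),
             different_ctd = congruency_effect(cells, "different_ctd"))
  tre <- trial_reinstatement(sim)
  bre <- block_reinstatement(sim)

  ct_univ <- event_univariate(ct_ps)
  trial_rt <- trial_rt_regression(behavior, tre, univariate = ct_univ)

  hip_ps <- exclude_events(sub$patterns$hippocampus, drop_run1 = FALSE)
  cc <- context_context_similarity(hip_ps)
  bls <- block_level_similarity(cc)
  names(bls)[-1] <- paste0("h_", names(bls)[-1])
  h_univ <- event_univariate(sub$patterns$hippocampus)
  h_univ <- h_univ[h_univ$class == "context_onset",
                   c("block_id", "univariate")]
  names(h_univ)[2] <- "h_univariate"
  c_univ <- event_univariate(sub$patterns$cortical)
  c_univ <- c_univ[c_univ$class == "context_onset",
                   c("block_id", "univariate")]
  names(c_univ)[2] <- "cortical_univariate"
  blocks <- Reduce(function(a, b) dplyr::left_join(a, b, by = "block_id"),
                   list(bre, bls, h_univ, c_univ))
  coupling <- block_coupling_regression(blocks)
  hippo_rt <- hippo_rt_regression(behavior, blocks)

  runs2 <- setdiff(sort(unique(cc$run_a)), 1L)
  h_same_ctd_mean <- mean(cc$z[cc$relation == "same_ctd" &
                                 cc$run_a %in% runs2 & cc$run_b %in% runs2])

  list(alphas = tibble::tibble(alpha_temporal = alphas[1],
                               alpha_contextual = alphas[2],
                               sse = if (is.null(gs)) NA_real_ else gs$sse),
       filter_counts = attr(behavior, "filter_counts"),
       rt_fit = rt_fit, acc_fit = acc_fit,
       cells = cells, contrast = contrast, congruency = congr,
       trial_rt = trial_rt, coupling = coupling, hippo_rt = hippo_rt,
       cc = cc, blocks = blocks, h_same_ctd_mean = h_same_ctd_mean)
}

collect_coefs <- function(results, element) {
  purrr::imap_dfr(results, function(res, i) {
    dplyr::mutate(tidy(res[[element]]), subject = as.integer(i),
                  .before = 1)
  })
}

#' Run the full synthetic study pipeline
#'
#' Simulates `n_subjects` sessions (with per-subject heterogeneity in the
#' hippocampal same-CTD correlation, propagated into the subject's
#' contextual-PE accuracy coefficient), analyzes every subject with
#' [analyze_subject()], and assembles group-level inference for each
#' reported family of tests.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `ctd_pipeline_result` with elements `config`,
#'   `subjects` (per-subject results), and `group` (named list of group
#'   tables).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  n <- config$n_subjects
  offs <- with_seed(derive_seed(config$seed, 9000), {
    rnorm(n, sd = config$rho_subject_sd)
  })
  # keep per-subject correlation targets inside the PSD-safe range
  offs <- pmin(pmax(offs, -0.14), 0.3)
  subjects <- vector("list", n)
  results <- vector("list", n)
  for (i in seq_len(n)) {
    gen_i <- config$gen
    gen_i$acc_pe_contextual <- gen_i$acc_pe_contextual +
      config$xs_coupling * offs[i]
    neural_i <- config$neural
    neural_i$rho_hippo_same_ctd <- neural_i$rho_hippo_same_ctd + offs[i]
    sub <- simulate_subject(config$design, gen_i, neural_i,
                            seed = derive_seed(config$seed, i))
    results[[i]] <- analyze_subject(
      sub, fit_alphas = config$fit_alphas, grid = config$grid,
      alphas = c(config$gen$alpha_temporal, config$gen$alpha_contextual),
      similarity_runs = config$similarity_runs)
    sub$patterns <- NULL   # keep the stored bundle light
    subjects[[i]] <- sub
  }

  rt_coefs <- collect_coefs(results, "rt_fit")
  acc_flagged <- which(vapply(results, function(r) r$acc_fit$flagged, TRUE))
  acc_coefs <- collect_coefs(results, "acc_fit")
  behavioral <- dplyr::bind_rows(
    dplyr::mutate(rt_coefs, model = "ols_logrt"),
    dplyr::mutate(acc_coefs, model = "logistic_accuracy")) |>
    dplyr::filter(.data$term %in% c("pe_temporal_z", "pe_contextual_z"))
  behavioral_group <- behavioral |>
    dplyr::mutate(term = paste(.data$model, .data$term, sep = ".")) |>
    (\(d) if (length(acc_flagged)) {
      d[!(grepl("logistic", d$term) & d$subject %in% acc_flagged), ]
    } else d)() |>
    group_inference()

  contrasts <- vapply(results, `[[`, 0, "contrast")
  congr <- t(vapply(results, `[[`, numeric(3), "congruency"))
  reinstatement_group <- dplyr::bind_rows(
    c(list(term = "interaction_contrast"), one_sample_t(contrasts)),
    c(list(term = "congruency_same_pooled"),
      one_sample_t(congr[, "same_pooled"])),
    c(list(term = "congruency_same_ctd"), one_sample_t(congr[, "same_ctd"])),
    c(list(term = "congruency_different_ctd"),
      one_sample_t(congr[, "different_ctd"])))

  cc_all <- purrr::imap_dfr(results, function(r, i) {
    dplyr::mutate(r$cc, subject = as.integer(i))
  })
  differentiation <- differentiation_tests(cc_all)

  coupling_coefs <- collect_coefs(results, "coupling")
  coupling_group <- group_inference(
    dplyr::filter(coupling_coefs, .data$term != "(Intercept)"))
  sim_terms <- c("h_same_context", "h_same_ctd", "h_different_ctd")
  coupling_group$q_value[coupling_group$term %in% sim_terms] <-
    bh_fdr(coupling_group$p_value[coupling_group$term %in% sim_terms])
  coupling_group$q_value[!coupling_group$term %in% sim_terms] <- NA_real_

  trial_rt_group <- group_inference(
    dplyr::filter(collect_coefs(results, "trial_rt"),
                  .data$term == "reinstatement"))
  hippo_rt_flagged <- which(vapply(results,
                                   function(r) r$hippo_rt$flagged, TRUE))
  hippo_rt_group <- group_inference(
    dplyr::filter(collect_coefs(results, "hippo_rt"),
                  grepl("^h_", .data$term),
                  !.data$subject %in% hippo_rt_flagged))

  h_sim <- vapply(results, `[[`, 0, "h_same_ctd_mean")
  acc_ctx <- acc_coefs$estimate[acc_coefs$term == "pe_contextual_z"]
  modulation <- -acc_ctx   # larger = stronger accuracy cost of surprise
  xs <- if (n >= 3) cross_subject_correlation(h_sim, modulation) else NULL

  alphas <- purrr::imap_dfr(results, function(r, i) {
    dplyr::mutate(r$alphas, subject = as.integer(i), .before = 1)
  })

  structure(list(
    config = config,
    subjects = subjects,
    results = results,
    group = list(behavioral = behavioral_group,
                 behavioral_coefs = behavioral,
                 reinstatement = reinstatement_group,
                 differentiation = differentiation,
                 coupling = coupling_group,
                 coupling_coefs = coupling_coefs,
                 trial_rt = trial_rt_group,
                 hippo_rt = hippo_rt_group,
                 cross_subject = xs,
                 alphas = alphas)),
    class = "ctd_pipeline_result")
}

#' @export
print.ctd_pipeline_result <- function(x, ...) {
  cat(sprintf("<ctd_pipeline_result> %d subjects (seed %s)\n",
              x$config$n_subjects, format(x$config$seed)))
  cat("\nBehavioral PE coefficients:\n")
  print(x$group$behavioral)
  cat("\nReinstatement (context-trial similarity):\n")
  print(x$group$reinstatement)
  cat("\nHippocampal context-context tests:\n")
  print(x$group$differentiation$tests)
  cat("\nCoupling (block-wise reinstatement ~ hippocampal measures):\n")
  print(x$group$coupling)
  invisible(x)
}

#' @method tidy ctd_pipeline_result
#' @export
tidy.ctd_pipeline_result <- function(x, ...) {
  grab <- function(tbl, family) {
    dplyr::mutate(tbl, family = family, .before = 1)
  }
  dplyr::bind_rows(
    grab(x$group$behavioral, "behavioral"),
    grab(x$group$reinstatement, "reinstatement"),
    grab(dplyr::rename(x$group$differentiation$tests,
                       term = "test"), "differentiation"),
    grab(x$group$coupling, "coupling"),
    grab(x$group$trial_rt, "trial_rt"),
    grab(x$group$hippo_rt, "hippo_rt"))
}

#' Write the pipeline's artifact bundle
#'
#' Emits TSV/JSON tables: per-subject behavioral coefficients, similarity
#' cells, coupling coefficients, fitted learning rates, subject events, and
#' a JSON group summary plus a line-oriented run log.
#'
#' @param res A `ctd_pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(res$group$behavioral_coefs,
                   file.path(dir, "behavioral_coefficients.tsv"))
  cells <- purrr::imap_dfr(res$results, function(r, i) {
    dplyr::mutate(r$cells, subject = as.integer(i), .before = 1)
  })
  readr::write_tsv(cells, file.path(dir, "similarity_cells.tsv"))
  readr::write_tsv(res$group$coupling_coefs,
                   file.path(dir, "coupling_coefficients.tsv"))
  readr::write_tsv(res$group$alphas, file.path(dir, "fitted_alphas.tsv"))
  summary <- tidy(res)
  readr::write_tsv(summary, file.path(dir, "group_summary.tsv"))
  jsonlite::write_json(
    list(n_subjects = res$config$n_subjects,
         seed = res$config$seed,
         group = split(summary, summary$family)),
    file.path(dir, "group_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  writeLines(sprintf("[%s] pipeline complete: %d subjects, %d group tables",
                     format(Sys.time()), res$config$n_subjects,
                     length(res$group)),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Type-I error / power calibration of the group tests
#'
#' Repeatedly simulates and analyzes a study under the given configuration
#' and under its null counterpart is the caller's choice: pass `config` or
#' `as_null_config(config)`. Collects the p-value of every headline group
#' test per replicate and reports rejection rates at `alpha` with
#' binomial confidence intervals.
#'
#' @param config A [pipeline_config()]; use `fit_alphas = FALSE` and reduced
#'   ROI sizes to keep replicates cheap.
#' @param n_replicates Number of simulated studies.
#' @param alpha Nominal level.
#' @param seed Seed for the replicate stream.
#' @return Tibble: `test`, `rejection_rate`, `ci_lower`, `ci_upper`,
#'   `n_replicates`.
#' @export
calibration_suite <- function(config, n_replicates = 20, alpha = 0.05,
                              seed = 1) {
  pvals <- purrr::map_dfr(seq_len(n_replicates), function(rep) {
    cfg <- config
    cfg$seed <- derive_seed(seed, rep)
    res <- run_pipeline(cfg)
    g <- res$group
    tibble::tibble(
      replicate = rep,
      test = c("rt_pe_temporal", "rt_pe_contextual", "acc_pe_contextual",
               "reinstatement_interaction", "differentiation",
               "coupling_h_same_ctd", "coupling_h_univariate",
               "trial_rt_reinstatement"),
      p = c(g$behavioral$p_value[g$behavioral$term ==
                                   "ols_logrt.pe_temporal_z"],
            g$behavioral$p_value[g$behavioral$term ==
                                   "ols_logrt.pe_contextual_z"],
            g$behavioral$p_value[g$behavioral$term ==
                                   "logistic_accuracy.pe_contextual_z"],
            g$reinstatement$p_value[g$reinstatement$term ==
                                      "interaction_contrast"],
            g$differentiation$tests$p_value[2],
            g$coupling$p_value[g$coupling$term == "h_same_ctd"],
            g$coupling$p_value[g$coupling$term == "h_univariate"],
            g$trial_rt$p_value[1]))
  })
  pvals |>
    dplyr::group_by(.data$test) |>
    dplyr::summarise(
      rejection_rate = mean(.data$p < alpha, na.rm = TRUE),
      ci_lower = stats::binom.test(sum(.data$p < alpha, na.rm = TRUE),
                                   dplyr::n())$conf.int[1],
      ci_upper = stats::binom.test(sum(.data$p < alpha, na.rm = TRUE),
                                   dplyr::n())$conf.int[2],
      n_replicates = dplyr::n(), .groups = "drop")
}
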