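#' Planted-truth parameters for synthetic multi-voxel patterns
#'
#' Encodes, as named generator parameters, every neural effect the analysis
#' stages test: context codes with controlled pairwise correlations, task
#' codes expressed at trial onsets, a congruency-dependent reinstatement of
#' the dominant-task code at context onset whose block-to-block gain is
#' coupled to hippocampal quantities, and hippocampal context codes whose
#' same-CTD similarity can decline across runs (differentiation).
#'
#' Correlation targets define the Gram matrix of the run-specific context
#' codes. Within a run the same-CTD target is met exactly by construction;
#' across runs the target for a pair of runs is the mean of the two runs'
#' values. `rho_hippo_same_ctd` may be a scalar or one value per run; the
#' default plants overlap in run 1 that collapses below `rho_hippo_diff_ctd`
#' afterwards, so hippocampal differentiation emerges over time.
#'
#' @param cortical_voxels,hippo_voxels Voxels per ROI. Each ROI needs at
#'   least `n_runs * n_contexts + 3` voxels for the orthonormal code basis.
#' @param rho_ctx_same_context,rho_ctx_same_ctd,rho_ctx_diff_ctd Cortical
#'   context-code correlation targets (same room across runs; different rooms
#'   sharing / not sharing a CTD).
#' @param rho_hippo_same_context,rho_hippo_same_ctd,rho_hippo_diff_ctd
#'   Hippocampal targets; `rho_hippo_same_ctd` scalar or per run.
#' @param amp_context,hippo_amp_context,amp_task Pattern amplitudes of the
#'   cortical context code, hippocampal context code and task code
#'   (arbitrary units; the hippocampal code is stronger so block-level
#'   similarity fluctuations are measurable against voxel noise).
#' @param gain_mean Baseline reinstatement gain at context onset: the
#'   dominant-task code enters the context-onset pattern scaled by
#'   `gain * amp_task`.
#' @param gain_hippo_fluct Coupling from the block's hippocampal same-CTD
#'   code-overlap fluctuation to the reinstatement gain.
#' @param gain_hippo_amp Coupling from the block's hippocampal univariate
#'   amplitude to the reinstatement gain.
#' @param gain_noise_sd SD of the block-level gain noise.
#' @param hippo_fluct_sd SD of the per-block fluctuation of the hippocampal
#'   same-CTD code overlap.
#' @param hippo_amp_sd SD of the per-block hippocampal univariate amplitude.
#' @param cortical_amp_coupling Optional confound: scales the cortical
#'   context-onset signal by `1 + coupling * amplitude` and adds the same
#'   amplitude to the ROI mean, so that apparent reinstatement co-varies with
#'   hippocampal univariate activity through signal-to-noise alone. Default 0.
#' @param noise_sd Voxel noise SD added to every event pattern.
#' @param ts_noise_sd Voxel noise SD for the optional time-series path.
#' @return An object of class `neural_params`.
#' @export
neural_params <- function(cortical_voxels = 120,
                          hippo_voxels = 80,
                          rho_ctx_same_context = 0.20,
                          rho_ctx_same_ctd = 0.05,
                          rho_ctx_diff_ctd = 0.05,
                          rho_hippo_same_context = 0.45,
                          rho_hippo_same_ctd = c(0.15, 0.01, 0.01,
                                                 0.01, 0.01, 0.01),
                          rho_hippo_diff_ctd = 0.14,
                          amp_context = 1,
                          hippo_amp_context = 3,
                          amp_task = 1,
                          gain_mean = 1,
                          gain_hippo_fluct = 1,
                          gain_hippo_amp = 0.6,
                          gain_noise_sd = 0.15,
                          hippo_fluct_sd = 0.8,
                          hippo_amp_sd = 1,
                          cortical_amp_coupling = 0,
                          noise_sd = 1,
                          ts_noise_sd = 1) {
  rhos <- c(rho_ctx_same_context, rho_ctx_same_ctd, rho_ctx_diff_ctd,
            rho_hippo_same_context, rho_hippo_same_ctd, rho_hippo_diff_ctd)
  if (!all(is.finite(rhos)) || any(abs(rhos) > 1)) {
    abort("correlation targets must lie in [-1, 1]",
          class = "ctdlearn_config_error")
  }
  if (noise_sd < 0 || ts_noise_sd < 0 || gain_noise_sd < 0 ||
      hippo_fluct_sd < 0 || hippo_amp_sd < 0) {
    abort("noise SDs must be non-negative", class = "ctdlearn_config_error")
  }
  structure(as.list(environment()), class = "neural_params")
}

# Gram matrix of run-specific context codes (n_runs * n_contexts square).
context_code_gram <- function(n_runs, n_contexts, ctd_assignment,
                              rho_same_context, rho_same_ctd, rho_diff_ctd) {
  if (length(rho_same_ctd) == 1) rho_same_ctd <- rep(rho_same_ctd, n_runs)
  if (length(rho_same_ctd) != n_runs) {
    abort("`rho_same_ctd` must be scalar or one value per run",
          class = "ctdlearn_config_error")
  }
  nc <- n_runs * n_contexts
  run_of <- rep(seq_len(n_runs), each = n_contexts)
  ctx_of <- rep(seq_len(n_contexts), n_runs)
  ctd_of <- ctd_assignment[ctx_of]
  g <- matrix(rho_diff_ctd, nc, nc)
  same_ctx <- outer(ctx_of, ctx_of, "==")
  same_ctd <- outer(ctd_of, ctd_of, "==")
  rr <- (outer(rho_same_ctd[run_of], rho_same_ctd[run_of], "+")) / 2
  g[same_ctd] <- rr[same_ctd]
  g[same_ctx] <- rho_same_context
  diag(g) <- 1
  g
}

# Orthonormal, mean-zero basis (V x k) plus codes with exact Gram `gram`.
# Returns list(codes = V x nc matrix, extra = V x n_extra orthonormal
# mean-zero vectors orthogonal to the codes).
build_codes <- function(n_voxels, gram, n_extra = 2) {
  k <- ncol(gram) + n_extra
  if (n_voxels < k + 1) {
    abort(sprintf("ROI needs at least %d voxels for the code basis", k + 1),
          class = "ctdlearn_config_error")
  }
  x <- matrix(rnorm(n_voxels * k), n_voxels, k)
  x <- sweep(x, 2, colMeans(x))           # orthogonal to the constant vector
  b <- qr.Q(qr(x))
  e <- eigen(gram, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    abort("context-code correlation targets imply a non-positive-semi-definite Gram matrix",
          class = "ctdlearn_config_error")
  }
  s <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  list(codes = b[, seq_len(ncol(gram)), drop = FALSE] %*% s,
       extra = b[, ncol(gram) + seq_len(n_extra), drop = FALSE])
}

#' Draw per-block latent neural states
#'
#' The block-level planted truth: a hippocampal same-CTD code-overlap
#' fluctuation, a hippocampal univariate amplitude, and the cortical
#' reinstatement gain composed from them,
#' `gain = gain_mean + gain_hippo_fluct * fluct + gain_hippo_amp * amp +
#' noise`.
#'
#' @param design A `session_design`.
#' @param nparams A [neural_params()] object.
#' @param seed Integer seed.
#' @return The design's `blocks` tibble with `hippo_fluct`, `hippo_amp` and
#'   `gain` columns.
#' @export
draw_block_states <- function(design, nparams = neural_params(), seed = 1) {
  b <- design$blocks
  with_seed(seed, {
    # block-level *fluctuations*: centered within session so they carry no
    # subject-level component (subject differences are planted separately)
    ctr <- function(x) x - mean(x)
    b$hippo_fluct <- ctr(rnorm(nrow(b), sd = nparams$hippo_fluct_sd))
    b$hippo_amp <- ctr(rnorm(nrow(b), sd = nparams$hippo_amp_sd))
    b$gain <- nparams$gain_mean +
      nparams$gain_hippo_fluct * b$hippo_fluct +
      nparams$gain_hippo_amp * b$hippo_amp +
      rnorm(nrow(b), sd = nparams$gain_noise_sd)
  })
  b
}

new_pattern_set <- function(pattern, events, roi) {
  stopifnot(nrow(pattern) == nrow(events))
  structure(list(pattern = pattern, events = events, roi = roi),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set> roi '%s': %d events x %d voxels (%s)\n",
              x$roi, nrow(x$pattern), ncol(x$pattern),
              paste(sprintf("%d %s", table(x$events$class),
                            names(table(x$events$class))), collapse = ", ")))
  invisible(x)
}

pattern_events <- function(design) {
  b <- design$blocks
  t <- design$trials
  nb <- nrow(b)
  nt <- nrow(t)
  tibble::new_tibble(list(
    class = rep(c("context_onset", "trial_cue"), c(nb, nt)),
    run = c(b$run, t$run), block = c(b$block, t$block),
    block_id = c(b$block_id, t$block_id),
    context = c(b$context, t$context), ctd = c(b$ctd, t$ctd),
    trial_id = c(rep(NA_integer_, nb), t$trial_id),
    task = c(rep(NA_integer_, nb), t$task),
    congruent = c(rep(NA, nb), t$congruent),
    onset = c(b$room_onset, t$cue_onset),
    event_id = seq_len(nb + nt)), nrow = nb + nt)
}

#' Generate event-level multi-voxel patterns for both ROIs
#'
#' Builds run-specific context codes with the exact target Gram matrix
#' (orthonormal mean-zero base vectors mixed through the symmetric square
#' root of the target correlation matrix), then composes event patterns:
#'
#' * cortical trial events: context code + task code of the required task,
#' * cortical context-onset events: context code + the *dominant*-task code
#'   scaled by the block's reinstatement gain,
#' * hippocampal context-onset events: context code, a per-block fluctuation
#'   of the same-CTD partner context's code, and a univariate amplitude,
#' * hippocampal trial events: context code only.
#'
#' Voxel-wise Gaussian noise (`noise_sd`) is added to every pattern.
#'
#' @param design A `session_design`.
#' @param nparams A [neural_params()] object.
#' @param seed Integer seed.
#' @param block_states Optional tibble from [draw_block_states()]; drawn
#'   internally (from `seed`) when omitted. Supplying it lets behavior and
#'   patterns share the same planted block states.
#' @return Named list of `pattern_set` objects (`cortical`, `hippocampus`),
#'   with the block states attached as attribute `"block_states"`.
#' @export
#' @examples
#' d <- generate_design(design_spec(n_runs = 2), seed = 1)
#' ps <- generate_patterns(d, neural_params(), seed = 1)
#' ps$cortical
generate_patterns <- function(design, nparams = neural_params(), seed = 1,
                              block_states = NULL) {
  spec <- design$spec
  if (is.null(block_states)) {
    block_states <- draw_block_states(design, nparams, derive_seed(seed, 101))
  }
  ev <- pattern_events(design)
  code_idx <- (ev$run - 1) * spec$n_contexts + ev$context
  # same-CTD partner context (other room with the same dominant task)
  partner <- vapply(seq_len(spec$n_contexts), function(c) {
    cand <- setdiff(which(spec$ctd_assignment == spec$ctd_assignment[c]), c)
    if (length(cand)) cand[1] else NA_integer_
  }, 1L)

  adapt_rho <- function(rho) {
    # per-run vectors adapt to the design: truncate, or extend with the
    # steady-state (last) value
    if (length(rho) == 1 || length(rho) == spec$n_runs) return(rho)
    if (length(rho) > spec$n_runs) rho[seq_len(spec$n_runs)] else
      c(rho, rep(rho[length(rho)], spec$n_runs - length(rho)))
  }
  make_roi <- function(n_vox, rho_sc, rho_sctd, rho_dctd, hippo) {
    gram <- context_code_gram(spec$n_runs, spec$n_contexts,
                              spec$ctd_assignment,
                              rho_sc, adapt_rho(rho_sctd), rho_dctd)
    cb <- build_codes(n_vox, gram, n_extra = 2)
    task_codes <- cb$extra                     # columns: face (0), object (1)
    amp_ctx <- if (hippo) nparams$hippo_amp_context else nparams$amp_context
    pat <- amp_ctx * t(cb$codes[, code_idx, drop = FALSE])
    is_ctx <- ev$class == "context_onset"
    st <- block_states[match(ev$block_id, block_states$block_id), ]
    if (hippo) {
      pidx <- (ev$run - 1) * spec$n_contexts + partner[ev$context]
      fl <- ifelse(is_ctx, st$hippo_fluct, 0)
      pat <- pat + (amp_ctx * fl) *
        t(cb$codes[, pidx, drop = FALSE])
      pat <- pat + ifelse(is_ctx, st$hippo_amp, 0)   # ROI-mean amplitude
    } else {
      g <- ifelse(is_ctx, st$gain, 0)
      dom_code <- t(task_codes[, ev$ctd + 1, drop = FALSE])
      tk <- ifelse(is_ctx, 0, 1)
      trial_code <- t(task_codes[, ifelse(is.na(ev$task), 1, ev$task) + 1,
                                 drop = FALSE])
      pat <- pat + (g * nparams$amp_task) * dom_code +
        (tk * nparams$amp_task) * trial_code
      if (nparams$cortical_amp_coupling != 0) {
        sc <- ifelse(is_ctx, 1 + nparams$cortical_amp_coupling * st$hippo_amp, 1)
        pat <- pat * sc +
          ifelse(is_ctx, nparams$cortical_amp_coupling * st$hippo_amp, 0)
      }
    }
    pat + matrix(rnorm(length(pat), sd = nparams$noise_sd),
                 nrow(pat), ncol(pat))
  }

  with_seed(seed, {
    cortical <- make_roi(nparams$cortical_voxels, nparams$rho_ctx_same_context,
                         nparams$rho_ctx_same_ctd, nparams$rho_ctx_diff_ctd,
                         hippo = FALSE)
    hippo <- make_roi(nparams$hippo_voxels, nparams$rho_hippo_same_context,
                      nparams$rho_hippo_same_ctd, nparams$rho_hippo_diff_ctd,
                      hippo = TRUE)
  })
  out <- list(cortical = new_pattern_set(cortical, ev, "cortical"),
              hippocampus = new_pattern_set(hippo, ev, "hippocampus"))
  attr(out, "block_states") <- block_states
  out
}

#' Generate synthetic voxel time series from event patterns
#'
#' Forward counterpart of the event GLM: each event contributes its pattern,
#' scaled by a canonical double-gamma HRF sampled at the TR grid and
#' time-locked to the event onset (a stick-function response). Additive
#' Gaussian voxel noise (`ts_noise_sd`). One series per run.
#'
#' @param design A `session_design`.
#' @param patterns A `pattern_set` (one ROI) from [generate_patterns()].
#' @param nparams A [neural_params()] object (for `ts_noise_sd`).
#' @param seed Integer seed.
#' @param tr Repetition time in seconds.
#' @param pad End padding in seconds after the last onset (HRF tail).
#' @param n_tr Optional fixed number of TRs per run; events whose onset falls
#'   beyond the series raise an error.
#' @return List, one element per run: `list(bold = TR x voxel matrix,
#'   events = event metadata tibble)`.
#' @export
generate_timeseries <- function(design, patterns, nparams = neural_params(),
                                seed = 1, tr = 2, pad = 32, n_tr = NULL) {
  ev <- patterns$events
  with_seed(seed, {
    lapply(seq_len(design$spec$n_runs), function(r) {
      sel <- ev$run == r
      onsets <- ev$onset[sel]
      nt <- n_tr %||% ceiling((max(onsets) + pad) / tr)
      if (any(onsets >= nt * tr)) {
        abort("event onset beyond the end of the time series",
              class = "ctdlearn_domain_error")
      }
      x <- build_design_matrix(onsets, n_tr = nt, tr = tr, nuisance = NULL)
      x <- x[, seq_along(onsets), drop = FALSE]   # event columns only
      bold <- x %*% patterns$pattern[sel, , drop = FALSE] +
        matrix(rnorm(nt * ncol(patterns$pattern), sd = nparams$ts_noise_sd),
               nt, ncol(patterns$pattern))
      list(bold = bold, events = ev[sel, , drop = FALSE])
    })
  })
}
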