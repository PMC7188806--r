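#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style canonical HRF: a gamma density peaking near 5 s minus a scaled
#' gamma undershoot peaking near 15 s, normalized to unit peak.
#'
#' @param t Time in seconds (vector); values before 0 return 0.
#' @param peak_delay,undershoot_delay Shape parameters of the response and
#'   undershoot gamma densities.
#' @param undershoot_ratio Undershoot amplitude relative to the response.
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                             undershoot_ratio = 1 / 6) {
  shape <- function(x) {
    dgamma(x, shape = peak_delay, rate = 1) -
      undershoot_ratio * dgamma(x, shape = undershoot_delay, rate = 1)
  }
  h <- shape(t)
  h[t < 0] <- 0
  h / max(shape(seq(0, 30, by = 0.01)))
}

#' Build an event design matrix (stick functions convolved with the HRF)
#'
#' One regressor per event: a single impulse at the event onset convolved
#' with the canonical double-gamma HRF and sampled at the TR grid. Nuisance
#' columns (at minimum an intercept) are appended after the event columns.
#'
#' @param onsets Event onsets in seconds, relative to series start.
#' @param n_tr Number of volumes.
#' @param tr Repetition time in seconds.
#' @param hrf Function of time (seconds) returning the impulse response.
#' @param nuisance Optional matrix of nuisance regressors (`n_tr` rows), or
#'   `NULL` for the default intercept-only set.
#' @return `n_tr` x (events + nuisance) matrix; event columns are named
#'   `ev1..evK`.
#' @export
build_design_matrix <- function(onsets, n_tr, tr = 2,
                                hrf = hrf_double_gamma, nuisance) {
  if (length(onsets) && any(onsets < 0 | onsets >= n_tr * tr)) {
    abort("event onset outside the sampled series", class = "ctdlearn_domain_error")
  }
  grid <- tr * (seq_len(n_tr) - 1)
  x <- vapply(onsets, function(o) hrf(grid - o), numeric(n_tr))
  x <- matrix(x, nrow = n_tr)
  colnames(x) <- if (length(onsets)) paste0("ev", seq_along(onsets))
  if (missing(nuisance)) nuisance <- matrix(1, n_tr, 1,
                                            dimnames = list(NULL, "const"))
  if (!is.null(nuisance)) x <- cbind(x, nuisance)
  x
}

#' Fit the event GLM at every voxel
#'
#' Per-voxel least squares of the BOLD series on the event design matrix,
#' returning event-level beta estimates and the residual series used for
#' noise normalization.
#'
#' @param bold `n_tr` x voxel matrix.
#' @param design Design matrix from [build_design_matrix()].
#' @param n_events Number of leading columns that are event regressors
#'   (defaults to all columns named `ev*`).
#' @return List with `betas` (event x voxel) and `residuals` (TR x voxel).
#' @export
fit_event_glm <- function(bold, design,
                          n_events = sum(grepl("^ev", colnames(design)))) {
  qrx <- qr(design)
  if (qrx$rank < ncol(design)) {
    bad <- colnames(design)[qrx$pivot[(qrx$rank + 1):ncol(design)]]
    abort(sprintf("design matrix is rank deficient (collinear columns: %s)",
                  paste(bad, collapse = ", ")),
          class = "ctdlearn_domain_error")
  }
  beta <- qr.coef(qrx, bold)
  list(betas = beta[seq_len(n_events), , drop = FALSE],
       residuals = bold - design %*% beta)
}

#' Multivariate noise normalization of event patterns
#'
#' Whitens event betas by the inverse symmetric square root of the voxel
#' residual covariance, `beta %*% solve(sqrtm(Sigma))`, with `Sigma` shrunk
#' toward its diagonal: `Sigma_sh = (1 - shrinkage) * Sigma + shrinkage *
#' diag(diag(Sigma))`. With an identity covariance the betas pass through
#' unchanged; with a diagonal covariance each voxel is divided by its
#' residual SD.
#'
#' @param betas Event x voxel matrix.
#' @param residuals TR x voxel residual matrix (at least 2 rows).
#' @param shrinkage Shrinkage weight toward the diagonal in \[0, 1\].
#' @return Normalized event x voxel matrix.
#' @export
noise_normalize <- function(betas, residuals, shrinkage = 0.1) {
  if (nrow(residuals) < 2) {
    abort("need at least 2 residual rows to estimate the covariance",
          class = "ctdlearn_domain_error")
  }
  stopifnot_scalar_prob(shrinkage, "shrinkage")
  sig <- stats::cov(residuals)
  sig <- (1 - shrinkage) * sig + shrinkage * diag(diag(sig), ncol(sig))
  e <- eigen(sig, symmetric = TRUE)
  if (min(e$values) <= 1e-12 * max(e$values)) {
    abort("residual covariance is singular; increase `shrinkage`",
          class = "ctdlearn_domain_error")
  }
  w <- e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
  out <- betas %*% w
  dimnames(out) <- dimnames(betas)
  out
}

#' ROI-mean (univariate) activity per event
#'
#' @param x A `pattern_set` or an event x voxel matrix.
#' @return Numeric vector, one mean amplitude per event.
#' @export
roi_univariate <- function(x) {
  m <- if (inherits(x, "pattern_set")) x$pattern else x
  rowMeans(m)
}

#' Apply event exclusions for similarity analyses
#'
#' Drops (i) trial events excluded from the behavioral analyses, (ii) events
#' with onset inside a window before a flagged outlier volume, and
#' (iii), when `drop_run1 = TRUE`, all run-1 events — learning is still in
#' progress during the first run, so similarity analyses start at run 2.
#'
#' @param ps A `pattern_set`.
#' @param include_trial_ids Trial ids retained by [filter_trials()]; `NULL`
#'   keeps all trials.
#' @param drop_run1 Exclude all run-1 events (default `TRUE`; the
#'   context-level validation analysis sets this to `FALSE`).
#' @param outlier_onsets Onsets (seconds) of flagged outlier volumes; events
#'   with onset in `(t - window, t]` for any flagged `t` are dropped.
#'   Synthetic sessions have none; the hook mirrors motion/variance
#'   censoring on real data.
#' @param window Exclusion window in seconds before an outlier volume.
#' @return The filtered `pattern_set`.
#' @export
exclude_events <- function(ps, include_trial_ids = NULL, drop_run1 = TRUE,
                           outlier_onsets = numeric(0), window = 12) {
  ev <- ps$events
  keep <- rep(TRUE, nrow(ev))
  if (!is.null(include_trial_ids)) {
    keep <- keep & (ev$class != "trial_cue" |
                      ev$trial_id %in% include_trial_ids)
  }
  if (drop_run1) keep <- keep & ev$run != 1
  for (t_out in outlier_onsets) {
    keep <- keep & !(ev$onset > t_out - window & ev$onset <= t_out)
  }
  new_pattern_set(ps$pattern[keep, , drop = FALSE],
                  ev[keep, , drop = FALSE], ps$roi)
}
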