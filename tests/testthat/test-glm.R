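test_that("a single stick event reproduces HRF samples in its column", {
  x <- build_design_matrix(onsets = 0, n_tr = 16, tr = 2, nuisance = NULL)
  expect_equal(x[, 1], hrf_double_gamma(2 * (0:15)))
  expect_equal(max(x[, 1]), 1, tolerance = 0.1)  # unit peak, TR sampling
})

test_that("well-separated events are nearly orthogonal; empty designs and
           out-of-range onsets behave as specified", {
  x <- build_design_matrix(onsets = c(0, 40), n_tr = 40, tr = 2,
                           nuisance = NULL)
  expect_lt(abs(stats::cor(x[, 1], x[, 2])), 0.12)

  x0 <- build_design_matrix(onsets = numeric(0), n_tr = 10, tr = 2)
  expect_equal(ncol(x0), 1)   # nuisance intercept only

  expect_error(build_design_matrix(onsets = 100, n_tr = 10, tr = 2),
               class = "ctdlearn_domain_error")
})

test_that("the event GLM inverts noiseless data and names collinear columns", {
  set.seed(1)
  x <- build_design_matrix(onsets = c(0, 14, 30), n_tr = 30, tr = 2)
  beta <- matrix(rnorm(4 * 6), 4, 6)
  y <- x %*% beta
  fit <- fit_event_glm(y, x)
  expect_equal(unname(fit$betas), unname(beta[1:3, ]), tolerance = 1e-8)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-8)

  xx <- cbind(x, dup = x[, 1])
  expect_error(fit_event_glm(y, xx), "collinear")
})

test_that("residual variance matches the injected noise level", {
  set.seed(2)
  x <- build_design_matrix(onsets = c(0, 20, 44, 70), n_tr = 60, tr = 2)
  beta <- matrix(rnorm(5 * 40), 5, 40)
  y <- x %*% beta + matrix(rnorm(60 * 40, sd = 0.5), 60, 40)
  fit <- fit_event_glm(y, x)
  sigma2 <- sum(fit$residuals^2) / ((60 - 5) * 40)
  expect_equal(sigma2, 0.25, tolerance = 0.05)
})

test_that("noise normalization has the documented exact special cases", {
  set.seed(3)
  betas <- matrix(rnorm(6 * 10), 6, 10)

  # identity covariance: unchanged (shrinkage keeps a diagonal diagonal)
  res_i <- matrix(rnorm(4000 * 10), 4000, 10)
  out <- noise_normalize(betas, res_i, shrinkage = 0)
  expect_equal(out, betas, tolerance = 0.1)

  # exactly diagonal covariance: divide by residual SDs
  res_d <- res_i %*% diag(seq(0.5, 5, length.out = 10))
  sig <- stats::cov(res_d)
  sig_diag <- diag(diag(sig), 10)
  out_d <- noise_normalize(betas, res_d, shrinkage = 1)  # pure diagonal
  expect_equal(out_d, betas %*% diag(1 / sqrt(diag(sig))), tolerance = 1e-8)
})

test_that("the inverse square root actually whitens the shrunk covariance", {
  set.seed(4)
  a <- matrix(rnorm(100), 10, 10)
  res <- matrix(rnorm(200 * 10), 200, 10) %*% a
  sig <- stats::cov(res)
  shr <- 0.1
  sig_sh <- (1 - shr) * sig + shr * diag(diag(sig), 10)
  e <- eigen(sig_sh, symmetric = TRUE)
  w <- e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
  expect_equal(w %*% w %*% sig_sh, diag(10), tolerance = 1e-8)
  # and the exported function applies exactly that transform
  betas <- matrix(rnorm(50), 5, 10)
  expect_equal(noise_normalize(betas, res, shrinkage = shr), betas %*% w,
               tolerance = 1e-10)
})

test_that("normalization commutes with voxel permutation", {
  set.seed(5)
  betas <- matrix(rnorm(40), 4, 10)
  res <- matrix(rnorm(500), 50, 10)
  perm <- sample(10)
  a <- noise_normalize(betas, res)[, perm]
  b <- noise_normalize(betas[, perm], res[, perm])
  expect_equal(unname(a), unname(b), tolerance = 1e-10)
})

test_that("normalization improves recovery of planted codes under
           correlated heteroscedastic noise", {
  set.seed(6)
  v <- 12
  code <- rnorm(v)
  mix <- diag(seq(0.2, 3, length.out = v))
  mix[1, 2] <- mix[2, 1] <- 1.5
  hits <- replicate(60, {
    noise_tr <- matrix(rnorm(40 * v), 40, v) %*% mix
    res <- matrix(rnorm(200 * v), 200, v) %*% mix
    betas <- matrix(rep(code, each = 40), 40, v) + noise_tr
    raw <- mean(apply(betas, 1, function(b) stats::cor(b, code)))
    wh <- noise_normalize(betas, res, shrinkage = 0.1)
    code_w <- noise_normalize(matrix(code, 1), res, shrinkage = 0.1)
    norm <- mean(apply(wh, 1, function(b) stats::cor(b, drop(code_w))))
    norm > raw
  })
  expect_gt(mean(hits), 0.7)
})

test_that("roi_univariate reduces patterns to event means", {
  m <- rbind(rep(2, 5), rep(0, 5), 1:5)
  expect_equal(roi_univariate(m), c(2, 0, 3))
})

test_that("event exclusion applies behavioral, run-1 and outlier-window rules", {
  sub <- quick_subject(seed = 3, n_runs = 2)
  ps <- sub$patterns$cortical
  keep_ids <- sub$design$trials$trial_id[1:50]

  out <- exclude_events(ps, include_trial_ids = keep_ids, drop_run1 = FALSE)
  expect_true(all(out$events$trial_id[out$events$class == "trial_cue"]
                  %in% keep_ids))
  expect_equal(sum(out$events$class == "context_onset"), 16)

  out1 <- exclude_events(ps, drop_run1 = TRUE)
  expect_false(any(out1$events$run == 1))

  # outlier volume at 100 s knocks out onsets in (88, 100]
  out2 <- exclude_events(ps, drop_run1 = FALSE, outlier_onsets = 100)
  gone <- setdiff(ps$events$event_id, out2$events$event_id)
  on <- ps$events$onset[match(gone, ps$events$event_id)]
  expect_true(all(on > 88 & on <= 100))
  expect_true(all(!(ps$events$onset > 88 & ps$events$onset <= 100) |
                    ps$events$event_id %in% gone))
})

test_that("time-series generation and GLM re-estimation round-trip patterns", {
  sub <- quick_subject(seed = 4, n_runs = 1)
  ps <- sub$patterns$cortical
  np0 <- quick_neural(ts_noise_sd = 0)

  ts <- generate_timeseries(sub$design, ps, np0, seed = 4)
  run1 <- ts[[1]]
  x <- build_design_matrix(run1$events$onset, n_tr = nrow(run1$bold), tr = 2)
  fit <- fit_event_glm(run1$bold, x)
  expect_equal(unname(fit$betas),
               unname(ps$pattern[ps$events$run == 1, ]), tolerance = 1e-6)

  # noiseless single event: the series is the outer product pattern x HRF
  one <- sub$patterns$cortical
  sel <- which(one$events$event_id == one$events$event_id[1])
  one$pattern <- one$pattern[sel, , drop = FALSE]
  one$events <- one$events[sel, , drop = FALSE]
  ts1 <- generate_timeseries(sub$design, one, np0, seed = 6, n_tr = 20)
  h <- hrf_double_gamma(2 * (0:19) - one$events$onset[1])
  expect_equal(unname(ts1[[1]]$bold), unname(outer(h, drop(one$pattern))),
               tolerance = 1e-10)

  expect_error(generate_timeseries(sub$design, ps, np0, seed = 7, n_tr = 3),
               class = "ctdlearn_domain_error")
})
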