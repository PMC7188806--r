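test_that("delta_update evaluates the update rule and guards its domain", {
  expect_equal(delta_update(0.5, 1, 0.1), 0.55)
  expect_equal(delta_update(0.37, 1, 0), 0.37)      # zero rate is identity
  expect_equal(delta_update(0.3, 0, 1), 0)          # full update jumps
  expect_error(delta_update(1.2, 1, 0.1), class = "ctdlearn_domain_error")
  expect_error(delta_update(0.5, 2, 0.1), class = "ctdlearn_domain_error")
  expect_error(delta_update(0.5, 1, 1.5), class = "ctdlearn_domain_error")
})

test_that("temporal learner matches the constant-task closed form", {
  # closed form: prediction entering trial t+1 is T + (p0 - T)(1 - a)^t
  for (alpha in c(0.1, 0.3, 0.97)) {
    for (target in 0:1) {
      fit <- run_temporal_model(rep(target, 12), alpha, p0 = 0.5)
      closed <- target + (0.5 - target) * (1 - alpha)^(0:11)
      expect_equal(fit$prediction, closed, tolerance = 1e-12)
      expect_equal(fit$pe, abs(target - closed), tolerance = 1e-12)
    }
  }
  fit <- run_temporal_model(c(1, 1, 1), alpha = 0.1)
  expect_equal(fit$pe, c(0.5, 0.45, 0.405))
  # post-sequence state = 1 - 0.5 * 0.9^3
  expect_equal(delta_update(fit$prediction[3], 1, 0.1), 0.6355)
})

test_that("alpha = 1 learner predicts the previous trial's task", {
  tasks <- c(1, 0, 0, 1, 1, 0)
  fit <- run_temporal_model(tasks, alpha = 1)
  expect_equal(fit$prediction[-1], tasks[-length(tasks)])
})

test_that("alternating tasks keep a small-alpha learner near 0.5", {
  alpha <- 0.05
  fit <- run_temporal_model(rep(c(1, 0), 50), alpha)
  late <- fit$prediction[21:100]
  expect_true(all(abs(late - 0.5) <= alpha + 1e-12))
})

test_that("predictions and errors are bounded for arbitrary sequences", {
  set.seed(42)
  for (i in 1:20) {
    tasks <- rbinom(60, 1, runif(1))
    ctx <- sample(1:4, 60, replace = TRUE)
    a <- runif(1)
    tm <- run_temporal_model(tasks, a)
    cm <- run_contextual_model(tasks, ctx, a)
    expect_true(all(tm$prediction >= 0 & tm$prediction <= 1))
    expect_true(all(tm$pe >= 0 & tm$pe <= 1))
    expect_true(all(cm$prediction >= 0 & cm$prediction <= 1))
    expect_true(all(cm$pe >= 0 & cm$pe <= 1))
  }
})

test_that("contextual model with one context equals the temporal model", {
  set.seed(7)
  tasks <- rbinom(40, 1, 0.75)
  tm <- run_temporal_model(tasks, 0.2)
  cm <- run_contextual_model(tasks, rep(3L, 40), 0.2)
  expect_equal(cm$prediction, tm$prediction, tolerance = 1e-12)
  expect_equal(cm$pe, tm$pe, tolerance = 1e-12)
})

test_that("contextual learners are independent across contexts", {
  # interleaved contexts with constant opposite tasks follow their own
  # closed forms on their own subsequences
  tasks <- rep(c(1, 0), 10)
  ctx <- rep(c(1, 2), 10)
  cm <- run_contextual_model(tasks, ctx, alpha = 0.3)
  closed1 <- 1 + (0.5 - 1) * 0.7^(0:9)
  closed2 <- 0 + (0.5 - 0) * 0.7^(0:9)
  expect_equal(cm$prediction[ctx == 1], closed1, tolerance = 1e-12)
  expect_equal(cm$prediction[ctx == 2], closed2, tolerance = 1e-12)
})

test_that("relabeling contexts leaves the error sequence unchanged", {
  set.seed(11)
  tasks <- rbinom(80, 1, 0.6)
  ctx <- sample(1:4, 80, replace = TRUE)
  perm <- c(3L, 4L, 1L, 2L)
  a <- run_contextual_model(tasks, ctx, 0.15)
  b <- run_contextual_model(tasks, perm[ctx], 0.15)
  expect_equal(a$pe, b$pe, tolerance = 1e-12)
})

test_that("unknown context ids and misaligned inputs raise errors", {
  expect_error(run_contextual_model(c(1, 0), c(1, 9), 0.1,
                                    context_set = 1:4),
               class = "ctdlearn_domain_error")
  expect_error(run_contextual_model(c(1, 0, 1), c(1, 2), 0.1),
               class = "ctdlearn_domain_error")
})

test_that("lagged error convention shifts the series by one trial", {
  tasks <- c(1, 1, 0, 1)
  plain <- run_temporal_model(tasks, 0.2)
  lag <- run_temporal_model(tasks, 0.2, lagged = TRUE)
  expect_equal(lag$pe[-1], plain$pe[-length(tasks)])
  expect_equal(lag$pe[1], plain$pe[1])
})

test_that("prediction_error recomputes |task - prediction|", {
  fit <- run_temporal_model(c(1, 0, 1), 0.25)
  expect_equal(prediction_error(fit, c(1, 0, 1)), fit$pe)
  expect_equal(prediction_error(fit, c(0, 1, 0)), 1 - fit$pe)
})

test_that("contextual predictions separate the two task demands over runs", {
  d <- generate_design(design_spec(), seed = 4)
  sep <- ctd_prediction_separation(d, alpha = 0.02)
  expect_equal(nrow(sep), 6)
  expect_true(all(diff(sep$separation) > 0))  # grows with exposure
  expect_gt(sep$separation[6], sep$separation[1])
})

test_that("grid search recovers on-lattice rates exactly from noise-free RT", {
  d <- generate_design(design_spec(), seed = 21)
  gen <- generative_params(alpha_temporal = 0.30, alpha_contextual = 0.10,
                           rt_noise_sd = 0)
  b <- generate_behavior(d, gen, seed = 21)
  b$included <- TRUE
  gs <- grid_search_alphas(b, grid = seq(0.05, 0.5, by = 0.05))
  expect_equal(gs$alpha_temporal, 0.30)
  expect_equal(gs$alpha_contextual, 0.10)
  expect_lt(gs$sse, 1e-8)
})

test_that("PE-independent RT yields the task-plus-constant SSE everywhere", {
  d <- generate_design(design_spec(n_runs = 2), seed = 5)
  b <- d$trials
  set.seed(5)
  b$log_rt <- 7 + 0.05 * b$task + rnorm(nrow(b), sd = 0.1)
  b$included <- TRUE
  grid <- c(0.1, 0.5, 0.9)
  gs <- grid_search_alphas(b, grid = grid)
  base <- sum(lm(log_rt ~ task, data = b)$residuals^2)
  # the PE regressors can only reduce the task+constant SSE
  expect_true(all(gs$sse_grid <= base + 1e-8))
  # dual route: every lattice cell equals an independent lm() refit
  for (i in seq_along(grid)) {
    pe_t <- run_temporal_model(b$task, grid[i])$pe
    for (j in seq_along(grid)) {
      pe_c <- run_contextual_model(b$task, b$context, grid[j])$pe
      oracle <- sum(lm(b$log_rt ~ pe_t + pe_c + b$task)$residuals^2)
      expect_equal(unname(gs$sse_grid[i, j]), oracle, tolerance = 1e-8)
    }
  }
})

test_that("grid search ties break toward the smallest contextual rate", {
  # constant RT in the PE dimension -> many near-ties; result must be the
  # lexicographically smallest (alpha_c, then alpha_t) among minimizers
  d <- generate_design(design_spec(n_runs = 1), seed = 9)
  b <- d$trials
  b$log_rt <- rep(7, nrow(b))
  b$log_rt[b$task == 1] <- 7.1
  b$included <- TRUE
  gs <- grid_search_alphas(b, grid = c(0.2, 0.4))
  ties <- which(gs$sse_grid <= gs$sse + 1e-12, arr.ind = TRUE)
  best <- ties[order(ties[, 2], ties[, 1]), , drop = FALSE][1, ]
  expect_equal(gs$alpha_temporal, gs$grid[best[1]])
  expect_equal(gs$alpha_contextual, gs$grid[best[2]])
})

test_that("grid search refuses fewer trials than regressors", {
  b <- tibble::tibble(task = c(0, 1, 0), context = c(1, 1, 2),
                      log_rt = c(7, 7.1, 7), included = TRUE)
  expect_error(grid_search_alphas(b, grid = c(0.1, 0.2)),
               class = "ctdlearn_domain_error")
})
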