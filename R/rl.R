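#' Delta-rule update
#'
#' One step of the delta rule: the prediction moves toward the observed task
#' by a fraction `alpha` of the prediction error,
#' `p + alpha * (target - p)`.
#'
#' @param p Current prediction, a probability in \[0, 1\].
#' @param target Observed task, 0 (face) or 1 (object).
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated prediction.
#' @export
#' @examples
#' delta_update(0.5, 1, 0.1)
delta_update <- function(p, target, alpha) {
  stopifnot_scalar_prob(alpha, "alpha")
  if (!all(p >= 0 & p <= 1)) {
    abort("`p` must lie in [0, 1]", class = "ctdlearn_domain_error")
  }
  if (!all(target %in% c(0, 1))) {
    abort("`target` must be 0 or 1", class = "ctdlearn_domain_error")
  }
  p + alpha * (target - p)
}

new_prediction_series <- function(prediction, pe, model) {
  tibble::tibble(trial = seq_along(prediction),
                 prediction = prediction, pe = pe, model = model)
}

#' Temporal delta-rule learner
#'
#' A single learner that predicts the upcoming task demand from the trial
#' sequence alone, ignoring context changes. The prediction attached to trial
#' `t` is the learner state *before* observing that trial's task; the unsigned
#' prediction error is `|task(t) - prediction(t)|` (set `lagged = TRUE` for
#' the variant that attaches the previous step's error to trial `t`, shifting
#' the error sequence by one trial).
#'
#' @param tasks Integer vector of observed tasks (0/1), in trial order.
#' @param alpha Learning rate in \[0, 1\].
#' @param p0 Initial prediction (default 0.5, neutral).
#' @param lagged If `TRUE`, attach `|task(t-1) - prediction(t-1)|` to trial
#'   `t` (first trial gets `|task(1) - p0|` so the series stays aligned).
#' @return A tibble with `trial`, `prediction`, `pe` and `model` columns.
#' @export
#' @examples
#' run_temporal_model(c(1, 1, 1), alpha = 0.1)
run_temporal_model <- function(tasks, alpha, p0 = 0.5, lagged = FALSE) {
  stopifnot_scalar_prob(alpha, "alpha")
  stopifnot_scalar_prob(p0, "p0")
  if (length(tasks) == 0) abort("`tasks` must be non-empty",
                                class = "ctdlearn_domain_error")
  if (!all(tasks %in% c(0, 1))) abort("`tasks` must be 0/1",
                                      class = "ctdlearn_domain_error")
  n <- length(tasks)
  pred <- numeric(n)
  p <- p0
  for (t in seq_len(n)) {
    pred[t] <- p
    p <- p + alpha * (tasks[t] - p)
  }
  pe <- abs(tasks - pred)
  if (lagged) pe <- c(pe[1], pe[-n])
  new_prediction_series(pred, pe, "temporal")
}

#' Contextual delta-rule learners
#'
#' One independent delta-rule learner per context, all sharing a single
#' learning rate. On each trial only the learner of the current context
#' predicts and updates; the other learners' states are untouched. With a
#' single context this reduces exactly to [run_temporal_model()].
#'
#' @inheritParams run_temporal_model
#' @param contexts Context id per trial, aligned with `tasks`.
#' @param context_set Optional vector of known context ids; trials with
#'   contexts outside this set raise an error. Defaults to the observed set.
#' @return A tibble with `trial`, `prediction`, `pe` and `model` columns.
#' @export
run_contextual_model <- function(tasks, contexts, alpha, p0 = 0.5,
                                 lagged = FALSE, context_set = NULL) {
  stopifnot_scalar_prob(alpha, "alpha")
  stopifnot_scalar_prob(p0, "p0")
  if (length(tasks) != length(contexts)) {
    abort("`contexts` must align with `tasks`", class = "ctdlearn_domain_error")
  }
  if (!all(tasks %in% c(0, 1))) abort("`tasks` must be 0/1",
                                      class = "ctdlearn_domain_error")
  ids <- context_set %||% sort(unique(contexts))
  if (!all(contexts %in% ids)) {
    abort(sprintf("unknown context id(s): %s",
                  paste(setdiff(unique(contexts), ids), collapse = ", ")),
          class = "ctdlearn_domain_error")
  }
  state <- setNames(rep(p0, length(ids)), as.character(ids))
  n <- length(tasks)
  pred <- numeric(n)
  for (t in seq_len(n)) {
    key <- as.character(contexts[t])
    pred[t] <- state[[key]]
    state[[key]] <- state[[key]] + alpha * (tasks[t] - state[[key]])
  }
  pe <- abs(tasks - pred)
  if (lagged) pe <- c(pe[1], pe[-n])
  out <- new_prediction_series(pred, pe, "contextual")
  attr(out, "final_state") <- state
  out
}

#' Unsigned prediction errors of a prediction series
#'
#' @param series Tibble from [run_temporal_model()] or
#'   [run_contextual_model()].
#' @param tasks Observed tasks aligned with the series.
#' @return Numeric vector of `|task - prediction|`, values in \[0, 1\].
#' @export
prediction_error <- function(series, tasks) {
  if (nrow(series) != length(tasks)) {
    abort("`tasks` must align with `series`", class = "ctdlearn_domain_error")
  }
  abs(tasks - series$prediction)
}

#' Separation of contextual predictions between the two task demands
#'
#' Runs the contextual learners over a design at a given learning rate and
#' returns, per run, the mean absolute difference between the predictions of
#' contexts whose dominant task is object and those whose dominant task is
#' face, averaged over that run's trials. Useful for judging how distinct the
#' two learned task demands are after a given amount of exposure.
#'
#' @param design A `session_design`.
#' @param alpha Learning rate.
#' @return Tibble with `run` and `separation`.
#' @export
ctd_prediction_separation <- function(design, alpha = 0.02) {
  tr <- design$trials
  fit <- run_contextual_model(tr$task, tr$context, alpha = alpha)
  tibble::tibble(run = tr$run, prediction = fit$prediction, ctd = tr$ctd) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(separation = mean(.data$prediction[.data$ctd == 1]) -
                       mean(.data$prediction[.data$ctd == 0]),
                     .groups = "drop")
}

# Prediction-error series for every alpha on a lattice, as a trials x
# n_alpha matrix. Vectorized over alphas for grid-search speed.
pe_matrix_temporal <- function(tasks, alphas, p0 = 0.5) {
  n <- length(tasks)
  k <- length(alphas)
  pe <- matrix(0, n, k)
  p <- rep(p0, k)
  for (t in seq_len(n)) {
    pe[t, ] <- abs(tasks[t] - p)
    p <- p + alphas * (tasks[t] - p)
  }
  pe
}

pe_matrix_contextual <- function(tasks, contexts, alphas, p0 = 0.5) {
  n <- length(tasks)
  k <- length(alphas)
  ids <- sort(unique(contexts))
  idx <- match(contexts, ids)
  state <- matrix(p0, length(ids), k)
  pe <- matrix(0, n, k)
  for (t in seq_len(n)) {
    ci <- idx[t]
    pe[t, ] <- abs(tasks[t] - state[ci, ])
    state[ci, ] <- state[ci, ] + alphas * (tasks[t] - state[ci, ])
  }
  pe
}

#' Grid search for the temporal and contextual learning rates
#'
#' For every pair of learning rates on the lattice, computes both
#' prediction-error series over the full trial sequence, regresses log-RT on
#' \{temporal PE, contextual PE, task, constant\} over the included trials
#' (one joint ordinary-least-squares fit), and records the residual sum of
#' squares. Returns the pair attaining the minimal SSE; ties are broken by the
#' smallest contextual rate, then the smallest temporal rate. Learning runs
#' over *all* trials (the learner observes every trial), whereas the
#' regression uses only trials flagged as included (error, post-error and
#' RT-outlier trials removed; see [filter_trials()]).
#'
#' @param behavior Tibble with `task`, `context`, `log_rt` and (optionally)
#'   `included` columns, in trial order.
#' @param grid Numeric vector of candidate learning rates (default
#'   `seq(0.01, 0.99, by = 0.01)`).
#' @param p0 Initial prediction.
#' @return An object of class `grid_search_result` with elements
#'   `alpha_temporal`, `alpha_contextual`, `sse` and the full `sse_grid`
#'   matrix (temporal rates in rows, contextual in columns).
#' @export
grid_search_alphas <- function(behavior,
                               grid = seq(0.01, 0.99, by = 0.01),
                               p0 = 0.5) {
  incl <- if ("included" %in% names(behavior)) behavior$included else
    rep(TRUE, nrow(behavior))
  y <- behavior$log_rt[incl]
  if (length(y) < 4) {
    abort("fewer included trials than regressors", class = "ctdlearn_domain_error")
  }
  task <- behavior$task[incl]
  pe_t <- pe_matrix_temporal(behavior$task, grid, p0)[incl, , drop = FALSE]
  pe_c <- pe_matrix_contextual(behavior$task, behavior$context, grid,
                               p0)[incl, , drop = FALSE]
  xb <- cbind(1, task)
  k <- length(grid)

  # Sufficient statistics for X'X and X'y over the whole lattice at once;
  # each (i, j) cell then needs only a 4x4 solve.
  bb <- crossprod(xb)                 # 2 x 2
  bt <- crossprod(xb, pe_t)           # 2 x k
  bc <- crossprod(xb, pe_c)           # 2 x k
  tt <- colSums(pe_t^2)               # k
  cc <- colSums(pe_c^2)               # k
  tc <- crossprod(pe_t, pe_c)         # k x k
  by <- crossprod(xb, y)              # 2
  ty <- as.numeric(crossprod(pe_t, y))
  cy <- as.numeric(crossprod(pe_c, y))
  yy <- sum(y^2)

  sse <- matrix(NA_real_, k, k, dimnames = list(format(grid), format(grid)))
  xtx <- matrix(0, 4, 4)
  xtx[1:2, 1:2] <- bb
  for (i in seq_len(k)) {
    xtx[3, 3] <- tt[i]
    xtx[1:2, 3] <- xtx[3, 1:2] <- bt[, i]
    for (j in seq_len(k)) {
      xtx[4, 4] <- cc[j]
      xtx[1:2, 4] <- xtx[4, 1:2] <- bc[, j]
      xtx[3, 4] <- xtx[4, 3] <- tc[i, j]
      xty <- c(by, ty[i], cy[j])
      beta <- tryCatch(solve(xtx, xty), error = function(e) NULL)
      sse[i, j] <- if (is.null(beta)) Inf else yy - sum(beta * xty)
    }
  }
  best <- which(sse <= min(sse) + 1e-12, arr.ind = TRUE)
  # ties: smallest contextual rate first, then smallest temporal rate
  best <- best[order(best[, 2], best[, 1]), , drop = FALSE][1, ]
  structure(list(alpha_temporal = grid[best[1]],
                 alpha_contextual = grid[best[2]],
                 sse = sse[best[1], best[2]],
                 grid = grid, sse_grid = sse,
                 n_included = length(y)),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> alpha_temporal = %.2f, alpha_contextual = %.2f (SSE %.4g over %d trials)\n",
              x$alpha_temporal, x$alpha_contextual, x$sse, x$n_included))
  invisible(x)
}

#' @method tidy grid_search_result
#' @export
tidy.grid_search_result <- function(x, ...) {
  tibble::tibble(term = c("alpha_temporal", "alpha_contextual"),
                 estimate = c(x$alpha_temporal, x$alpha_contextual))
}

#' @method glance grid_search_result
#' @export
glance.grid_search_result <- function(x, ...) {
  tibble::tibble(sse = x$sse, n_included = x$n_included,
                 grid_size = length(x$grid))
}
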