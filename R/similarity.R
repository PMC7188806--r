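FISHER_CLAMP <- 1 - 1e-7

#' Fisher-transformed Pearson correlation
#'
#' Pearson's r computed from centered cross-products, clamped to
#' `1 - 1e-7` in magnitude (so degenerate, perfectly correlated inputs give a
#' finite value), then Fisher z-transformed with `atanh`.
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return The Fisher z value.
#' @export
#' @examples
#' fisher_pearson(c(1, 2, 3), c(1, 2, 4))
fisher_pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must be equal-length vectors of length >= 3",
          class = "ctdlearn_domain_error")
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sum(xc^2)
  sy <- sum(yc^2)
  if (sx == 0 || sy == 0) {
    abort("zero variance input to `fisher_pearson`",
          class = "ctdlearn_degenerate_error")
  }
  r <- sum(xc * yc) / sqrt(sx * sy)
  atanh(pmin(pmax(r, -FISHER_CLAMP), FISHER_CLAMP))
}

# Fisher-z correlation matrix between the rows of two pattern matrices.
fisher_cor_rows <- function(a, b) {
  rs <- function(m) {
    m <- m - rowMeans(m)
    n <- sqrt(rowSums(m^2))
    if (any(n == 0)) abort("zero-variance pattern row",
                           class = "ctdlearn_degenerate_error")
    m / n
  }
  r <- tcrossprod(rs(a), rs(b))
  atanh(pmin(pmax(r, -FISHER_CLAMP), FISHER_CLAMP))
}

#' Label a context/trial (or context/context) pair
#'
#' Context relation: `same_context` when the two events share a room,
#' `same_ctd` for different rooms with the same dominant task, otherwise
#' `different_ctd`. Trial congruency is defined relative to the trial's own
#' context: `congruent` when the trial's required task equals its context's
#' dominant task.
#'
#' @param context_a,context_b Room ids.
#' @param ctd_a,ctd_b Dominant tasks (0/1).
#' @param congruent Optional logical, the trial's congruency flag; when
#'   supplied the returned tibble gains a `congruency` column.
#' @return Tibble with `relation` (and `congruency`).
#' @export
label_pair <- function(context_a, context_b, ctd_a, ctd_b, congruent = NULL) {
  relation <- dplyr::case_when(
    context_a == context_b ~ "same_context",
    ctd_a == ctd_b ~ "same_ctd",
    TRUE ~ "different_ctd")
  out <- tibble::tibble(relation = relation)
  if (!is.null(congruent)) {
    out$congruency <- ifelse(congruent, "congruent", "incongruent")
  }
  out
}

#' Cross-run context-trial pattern similarity
#'
#' Fisher-z Pearson correlation between every context-onset pattern and every
#' out-of-run trial-cue pattern, restricted to `runs` (run 1 is excluded by
#' default because learning is still in progress there). Each pair is labeled
#' with the 3 x 2 factorial condition: context relation (same context /
#' same CTD / different CTD) by trial congruency.
#'
#' @param ps A `pattern_set` containing `context_onset` and `trial_cue`
#'   events (typically already passed through [exclude_events()]).
#' @param runs Runs to use (default: all available runs except run 1, or all
#'   runs if only run-2+ events remain).
#' @return Tibble with one row per cross-run pair: event ids, runs, the
#'   trial's id and block, `relation`, `congruency` and `z`.
#' @export
context_trial_similarity <- function(ps, runs = NULL) {
  ev <- ps$events
  runs <- runs %||% setdiff(sort(unique(ev$run)), 1L)
  ci <- which(ev$class == "context_onset" & ev$run %in% runs)
  ti <- which(ev$class == "trial_cue" & ev$run %in% runs)
  if (!length(ci) || !length(ti)) {
    abort("no context-onset / trial-cue events in the requested runs",
          class = "ctdlearn_domain_error")
  }
  z <- fisher_cor_rows(ps$pattern[ci, , drop = FALSE],
                       ps$pattern[ti, , drop = FALSE])
  cross <- outer(ev$run[ci], ev$run[ti], "!=")
  idx <- which(cross, arr.ind = TRUE)
  a <- ci[idx[, 1]]
  b <- ti[idx[, 2]]
  relation <- rep("different_ctd", length(a))
  relation[ev$ctd[a] == ev$ctd[b]] <- "same_ctd"
  relation[ev$context[a] == ev$context[b]] <- "same_context"
  tibble::new_tibble(list(
    ctx_event = ev$event_id[a], trial_event = ev$event_id[b],
    run_ctx = ev$run[a], run_trial = ev$run[b],
    ctx_block = ev$block_id[a], trial_block = ev$block_id[b],
    trial_id = ev$trial_id[b],
    relation = relation,
    congruency = c("incongruent", "congruent")[ev$congruent[b] + 1L],
    z = z[idx]), nrow = length(a))
}

relation_levels <- c("same_context", "same_ctd", "different_ctd")

#' Condition-cell means of a similarity table
#'
#' Unweighted mean Fisher z per cell of the 3 (context relation) x 2
#' (congruency) factorial. Empty cells are returned with `NA` and flagged
#' via the `missing` column; frequency imbalance across cells is handled by
#' the contrast weights, not by reweighting here.
#'
#' @param table Output of [context_trial_similarity()].
#' @return Tibble with `relation`, `congruency`, `mean_z`, `n`, `missing`.
#' @export
cell_means <- function(table) {
  keys <- paste(rep(relation_levels, each = 2),
                c("congruent", "incongruent"), sep = ".")
  idx <- match(paste(table$relation, table$congruency, sep = "."), keys)
  n <- tabulate(idx, nbins = 6)
  sums <- numeric(6)
  agg <- rowsum(table$z, idx)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  tibble::tibble(
    relation = rep(relation_levels, each = 2),
    congruency = rep(c("congruent", "incongruent"), 3),
    mean_z = ifelse(n > 0, sums / n, NA_real_),
    n = n, missing = n == 0L)
}

#' Interaction-contrast weights for CTD reinstatement
#'
#' The context-relation x congruency interaction contrast over the six cells
#' (same context, same CTD, different CTD) x (congruent, incongruent):
#' weights (+1, -1, +1, -1, -2, +2). The double weight on the Different-CTD
#' cells accounts for their doubled trial frequency and makes the contrast
#' orthogonal to both main effects; both properties are asserted at
#' construction.
#'
#' @param normalize Divide by the sum of absolute weights.
#' @return Named numeric vector keyed `relation.congruency`.
#' @export
ctd_contrast_weights <- function(normalize = FALSE) {
  w <- c(same_context.congruent = 1, same_context.incongruent = -1,
         same_ctd.congruent = 1, same_ctd.incongruent = -1,
         different_ctd.congruent = -2, different_ctd.incongruent = 2)
  stopifnot(sum(w) == 0,
            sum(w * c(1, -1, 1, -1, 1, -1)) == 0,   # congruency main effect
            sum(w * c(1, 1, 1, 1, -2, -2)) == 0)    # relation main effect
  if (normalize) w <- w / sum(abs(w))
  w
}

#' Reinstatement interaction contrast
#'
#' Weighted sum of the six condition-cell means with the
#' [ctd_contrast_weights()]; positive values indicate
#' congruency-dependent reinstatement of the dominant task demand.
#'
#' @param cells Output of [cell_means()].
#' @param weights Contrast weights keyed `relation.congruency`.
#' @return Scalar contrast value.
#' @export
reinstatement_contrast <- function(cells, weights = ctd_contrast_weights()) {
  key <- paste(cells$relation, cells$congruency, sep = ".")
  if (any(cells$missing)) {
    abort(sprintf("empty condition cell(s): %s",
                  paste(key[cells$missing], collapse = ", ")),
          class = "ctdlearn_degenerate_error")
  }
  sum(weights[key] * cells$mean_z)
}

#' Congruency effect within a subset of context relations
#'
#' Congruent-minus-incongruent difference of cell means. `same_pooled`
#' averages the Same Context and Same CTD cells (per congruency) before
#' differencing; the other subsets use their single pair of cells.
#'
#' @param cells Output of [cell_means()].
#' @param subset One of `"same_pooled"`, `"same_context"`, `"same_ctd"`,
#'   `"different_ctd"`.
#' @return Scalar effect.
#' @export
congruency_effect <- function(cells, subset = c("same_pooled", "same_context",
                                                "same_ctd", "different_ctd")) {
  subset <- match.arg(subset)
  rel <- if (subset == "same_pooled") c("same_context", "same_ctd") else subset
  sub <- cells[cells$relation %in% rel, ]
  if (any(sub$missing)) {
    abort("empty condition cell in the requested subset",
          class = "ctdlearn_degenerate_error")
  }
  mean(sub$mean_z[sub$congruency == "congruent"]) -
    mean(sub$mean_z[sub$congruency == "incongruent"])
}

#' Trial-level reinstatement score
#'
#' For each trial, the mean Fisher z of its pairs in the Same Context and
#' Same CTD relations (the Different-CTD condition is excluded so the score
#' is not confounded by CTD mismatch between contexts), signed +1 for
#' congruent and -1 for incongruent trials. Trials without eligible pairs
#' are absent from the output.
#'
#' @param table Output of [context_trial_similarity()].
#' @return Tibble with `trial_id`, `trial_block` and `reinstatement`.
#' @export
trial_reinstatement <- function(table) {
  keep <- table$relation != "different_ctd"
  tid <- table$trial_id[keep]
  ids <- sort(unique(tid))
  f <- factor(tid, levels = ids)
  m <- unname(rowsum(table$z[keep], f)[, 1]) / tabulate(f)
  first <- match(ids, tid)   # one representative pair per trial
  sign <- ifelse(table$congruency[keep][first] == "congruent", 1, -1)
  tibble::tibble(trial_id = ids,
                 trial_block = table$trial_block[keep][first],
                 reinstatement = m * sign)
}

#' Block-level reinstatement
#'
#' The match/mismatch contrast evaluated at each block's context onset: the
#' mean congruency-signed Fisher z over the same-relation pairs that involve
#' the block's context-onset pattern (Different CTD excluded, as in the
#' trial-level measure). Reinstatement happens at the room onset, so this is
#' the block-resolved reinstatement strength used as the outcome of the
#' hippocampal-cortical coupling regression.
#'
#' @param table Output of [context_trial_similarity()].
#' @return Tibble with `block_id`, `reinstatement` and `n_pairs`.
#' @export
block_reinstatement <- function(table) {
  keep <- table$relation != "different_ctd"
  ids <- sort(unique(table$ctx_block[keep]))
  f <- factor(table$ctx_block[keep], levels = ids)
  zs <- table$z[keep] *
    ifelse(table$congruency[keep] == "congruent", 1, -1)
  n <- tabulate(f)
  tibble::tibble(block_id = ids,
                 reinstatement = unname(rowsum(zs, f)[, 1]) / n,
                 n_pairs = n)
}

#' Cross-run context-context pattern similarity
#'
#' Fisher-z Pearson correlation between every pair of context-onset patterns
#' from different runs (one pattern per block, so pattern separation can be
#' tracked block by block). Conditions are the three context relations; no
#' congruency factor applies.
#'
#' @param ps A `pattern_set` with `context_onset` events.
#' @param runs Runs to include (default: all — the context-level validation
#'   test uses all six runs).
#' @return Tibble with one row per unordered cross-run pair.
#' @export
context_context_similarity <- function(ps, runs = NULL) {
  ev <- ps$events
  runs <- runs %||% sort(unique(ev$run))
  ci <- which(ev$class == "context_onset" & ev$run %in% runs)
  if (length(ci) < 2) abort("need at least two context-onset events",
                            class = "ctdlearn_domain_error")
  z <- fisher_cor_rows(ps$pattern[ci, , drop = FALSE],
                       ps$pattern[ci, , drop = FALSE])
  idx <- which(upper.tri(z) & outer(ev$run[ci], ev$run[ci], "!="),
               arr.ind = TRUE)
  a <- ci[idx[, 1]]
  b <- ci[idx[, 2]]
  relation <- rep("different_ctd", length(a))
  relation[ev$ctd[a] == ev$ctd[b]] <- "same_ctd"
  relation[ev$context[a] == ev$context[b]] <- "same_context"
  tibble::new_tibble(list(
    event_a = ev$event_id[a], event_b = ev$event_id[b],
    run_a = ev$run[a], run_b = ev$run[b],
    block_a = ev$block_id[a], block_b = ev$block_id[b],
    context_a = ev$context[a], context_b = ev$context[b],
    relation = relation,
    z = z[idx]), nrow = length(a))
}

#' Per-condition means of a context-context similarity table
#'
#' @param cc Output of [context_context_similarity()].
#' @param runs Optional run restriction (pairs with *both* runs in `runs`).
#' @return Tibble with `relation` and `mean_z`.
#' @export
cc_condition_means <- function(cc, runs = NULL) {
  if (!is.null(runs)) cc <- cc[cc$run_a %in% runs & cc$run_b %in% runs, ]
  f <- factor(cc$relation)
  tibble::tibble(relation = levels(f),
                 mean_z = unname(rowsum(cc$z, f)[, 1]) / tabulate(f),
                 n = tabulate(f))
}

#' Context-level validation and differentiation tests
#'
#' Group-level paired t-tests on per-subject context-context condition
#' means: (i) validation — Same Context vs Different CTD over all runs
#' (context identity is coded from the start, so no learning assumption is
#' needed); (ii) differentiation — Same CTD vs Different CTD, by default over
#' runs 2+ (differentiation of overlapping contexts emerges with learning).
#' A run-wise condition-mean profile is returned alongside.
#'
#' @param cc_all Tibble of per-subject context-context tables bound together,
#'   with a `subject` column.
#' @param differentiation_runs Runs for the differentiation test (`NULL` =
#'   all runs except run 1).
#' @return List of class `ctd_differentiation`: `tests` (one row per test
#'   with group stats), `subject_means`, and `run_profile` (group mean z per
#'   relation and run, a pair contributing to both of its runs).
#' @export
differentiation_tests <- function(cc_all, differentiation_runs = NULL) {
  runs_all <- sort(unique(c(cc_all$run_a, cc_all$run_b)))
  differentiation_runs <- differentiation_runs %||% setdiff(runs_all, 1L)

  means_by <- function(cc, runs) {
    cc |>
      dplyr::filter(.data$run_a %in% runs & .data$run_b %in% runs) |>
      dplyr::group_by(.data$subject, .data$relation) |>
      dplyr::summarise(mean_z = mean(.data$z), .groups = "drop")
  }
  m_all <- means_by(cc_all, runs_all)
  m_diff <- means_by(cc_all, differentiation_runs)
  wide <- function(m) tidyr::pivot_wider(m, names_from = "relation",
                                         values_from = "mean_z")
  w_all <- wide(m_all)
  w_diff <- wide(m_diff)

  tests <- dplyr::bind_rows(
    c(list(test = "validation_same_context_vs_different_ctd",
           runs = paste(range(runs_all), collapse = "-"),
           mean_a = mean(w_all$same_context),
           mean_b = mean(w_all$different_ctd)),
      paired_t(w_all$same_context, w_all$different_ctd)),
    c(list(test = "differentiation_same_ctd_vs_different_ctd",
           runs = paste(range(differentiation_runs), collapse = "-"),
           mean_a = mean(w_diff$same_ctd),
           mean_b = mean(w_diff$different_ctd)),
      paired_t(w_diff$same_ctd, w_diff$different_ctd)))

  run_profile <- cc_all |>
    tidyr::pivot_longer(c("run_a", "run_b"), values_to = "run") |>
    dplyr::group_by(.data$subject, .data$relation, .data$run) |>
    dplyr::summarise(mean_z = mean(.data$z), .groups = "drop") |>
    dplyr::group_by(.data$relation, .data$run) |>
    dplyr::summarise(mean_z = mean(.data$mean_z), .groups = "drop")

  structure(list(tests = tests, subject_means = m_all,
                 run_profile = run_profile),
            class = "ctd_differentiation")
}

#' @export
print.ctd_differentiation <- function(x, ...) {
  cat("<ctd_differentiation>\n")
  print(x$tests)
  invisible(x)
}
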