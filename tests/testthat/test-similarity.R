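make_sim_table <- function(relation, congruency, z) {
  n <- length(z)
  tibble::tibble(
    ctx_event = seq_len(n), trial_event = seq_len(n) + 100,
    run_ctx = 2L, run_trial = 3L, ctx_block = seq_len(n),
    trial_block = seq_len(n) + 8L, trial_id = seq_len(n),
    relation = relation, congruency = congruency, z = z)
}

test_that("fisher_pearson matches an independent cor + atanh oracle", {
  expect_equal(fisher_pearson(c(1, 2, 3), c(1, 2, 4)),
               oracle_fisher(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(fisher_pearson(c(1, 2, 3), c(1, 2, 4)), 2.3502,
               tolerance = 1e-4)
  set.seed(8)
  for (i in 1:25) {
    x <- rnorm(10)
    y <- rnorm(10)
    expect_equal(fisher_pearson(x, y), oracle_fisher(x, y),
                 tolerance = 1e-12)
  }
  # mean-centered orthogonal vectors -> exactly 0
  expect_equal(fisher_pearson(c(-1, 0, 1), c(1, -2, 1)), 0)
})

test_that("fisher_pearson clamps perfect correlation and guards its domain", {
  x <- c(1, 2, 5)
  expect_equal(fisher_pearson(x, x), atanh(1 - 1e-7))
  expect_equal(fisher_pearson(x, -2 * x), -atanh(1 - 1e-7))
  expect_error(fisher_pearson(c(1, 1, 1), c(1, 2, 3)),
               class = "ctdlearn_degenerate_error")
  expect_error(fisher_pearson(c(1, 2), c(1, 2)),
               class = "ctdlearn_domain_error")
})

test_that("pair labeling follows room identity, shared CTD and congruency", {
  expect_equal(label_pair(1, 1, 0, 0, congruent = TRUE),
               tibble::tibble(relation = "same_context",
                              congruency = "congruent"))
  expect_equal(label_pair(1, 2, 1, 1, congruent = FALSE),
               tibble::tibble(relation = "same_ctd",
                              congruency = "incongruent"))
  expect_equal(label_pair(1, 3, 0, 1)$relation, "different_ctd")
  expect_equal(label_pair(1, 3, 1, 0)$relation, "different_ctd")
})

test_that("context-trial tables contain every cross-run pair and no others", {
  sub <- quick_subject(seed = 10)
  ps <- exclude_events(sub$patterns$cortical, drop_run1 = TRUE)
  tab <- context_trial_similarity(ps)
  ev <- ps$events
  # combinatorial oracle: per context event, trials in the other runs
  n_ctx <- sum(ev$class == "context_onset")
  expected <- sum(vapply(which(ev$class == "context_onset"), function(i) {
    sum(ev$class == "trial_cue" & ev$run != ev$run[i])
  }, 0))
  expect_equal(nrow(tab), expected)
  expect_equal(n_ctx, 40)
  expect_true(all(tab$run_ctx != tab$run_trial))
  expect_false(any(tab$run_ctx == 1 | tab$run_trial == 1))
  expect_false(any(duplicated(tab[c("ctx_event", "trial_event")])))
})

test_that("identical patterns give the clamped constant similarity", {
  sub <- quick_subject(seed = 11, n_runs = 2)
  ps <- sub$patterns$cortical
  ps$pattern <- matrix(rep(rnorm(ncol(ps$pattern)), each = nrow(ps$pattern)),
                       nrow(ps$pattern), byrow = FALSE)
  ps$pattern <- ps$pattern + 0  # identical rows
  ps$pattern[] <- rep(rnorm(ncol(ps$pattern)), each = nrow(ps$pattern))
  tab <- context_trial_similarity(ps, runs = 1:2)
  expect_true(all(tab$z == atanh(1 - 1e-7)))
})

test_that("cell means average exactly and flag empty cells", {
  tab <- make_sim_table(
    relation = c("same_context", "same_context", "same_ctd",
                 "same_ctd", "different_ctd"),
    congruency = c("congruent", "congruent", "incongruent",
                   "incongruent", "congruent"),
    z = c(0.2, 0.4, 0.1, 0.3, -0.5))
  cells <- cell_means(tab)
  expect_equal(cells$mean_z[cells$relation == "same_context" &
                              cells$congruency == "congruent"], 0.3)
  expect_equal(cells$mean_z[cells$relation == "same_ctd" &
                              cells$congruency == "incongruent"], 0.2)
  expect_equal(cells$mean_z[cells$relation == "different_ctd" &
                              cells$congruency == "congruent"], -0.5)
  expect_true(cells$missing[cells$relation == "same_ctd" &
                              cells$congruency == "congruent"])
  expect_equal(sum(cells$missing), 3)
  expect_error(reinstatement_contrast(cells),
               class = "ctdlearn_degenerate_error")
})

test_that("interaction contrast weights satisfy their invariants", {
  w <- ctd_contrast_weights()
  expect_equal(sum(w), 0)
  expect_equal(sum(w * c(1, -1, 1, -1, 1, -1)), 0)
  expect_equal(sum(w * c(1, 1, 1, 1, -2, -2)), 0)
  expect_equal(unname(w["different_ctd.congruent"]), -2)
  wn <- ctd_contrast_weights(normalize = TRUE)
  expect_equal(sum(abs(wn)), 1)
})

test_that("reinstatement contrast is the stated weighted sum", {
  cells6 <- function(z) {
    tidyr::expand_grid(relation = c("same_context", "same_ctd",
                                    "different_ctd"),
                       congruency = c("congruent", "incongruent")) |>
      dplyr::mutate(mean_z = z, n = 10L, missing = FALSE)
  }
  expect_equal(reinstatement_contrast(cells6(rep(0.3, 6))), 0)
  # cells (sc_con, sc_inc, sctd_con, sctd_inc, dctd_con, dctd_inc)
  expect_equal(reinstatement_contrast(cells6(c(1, 0, 1, 0, 0, 0))), 2)
  expect_equal(reinstatement_contrast(cells6(c(0.5, 0.1, 0.4, 0.2,
                                               0.1, 0.3))),
               0.5 - 0.1 + 0.4 - 0.2 - 2 * 0.1 + 2 * 0.3)
})

test_that("congruency effects isolate the requested subset linearly", {
  cells6 <- function(z) {
    tidyr::expand_grid(relation = c("same_context", "same_ctd",
                                    "different_ctd"),
                       congruency = c("congruent", "incongruent")) |>
      dplyr::mutate(mean_z = z, n = 10L, missing = FALSE)
  }
  delta <- 0.25
  planted <- cells6(c(0.1 + delta, 0.1, 0.1 + delta, 0.1, 0.1, 0.1))
  expect_equal(congruency_effect(planted, "same_pooled"), delta)
  expect_equal(congruency_effect(planted, "different_ctd"), 0)
  expect_equal(congruency_effect(cells6(rep(0.4, 6)), "same_ctd"), 0)
  flipped <- cells6(-c(0.1 + delta, 0.1, 0.1 + delta, 0.1, 0.1, 0.1))
  expect_equal(congruency_effect(flipped, "same_pooled"), -delta)
})

test_that("trial and block reinstatement apply the match/mismatch sign", {
  tab <- dplyr::bind_rows(
    make_sim_table(rep("same_context", 2), rep("congruent", 2),
                   c(0.3, 0.5)) |>
      dplyr::mutate(trial_id = 1L, trial_block = 9L, ctx_block = 1:2),
    make_sim_table("same_ctd", "incongruent", 0.4) |>
      dplyr::mutate(trial_id = 2L, trial_block = 9L, ctx_block = 1L),
    make_sim_table("different_ctd", "congruent", 5) |>
      dplyr::mutate(trial_id = 1L, trial_block = 9L, ctx_block = 3L))
  tre <- trial_reinstatement(tab)
  expect_equal(tre$reinstatement[tre$trial_id == 1], 0.4)   # mean(0.3, 0.5)
  expect_equal(tre$reinstatement[tre$trial_id == 2], -0.4)  # mismatch sign

  bre <- block_reinstatement(tab)
  # block 1: pairs (0.3 congruent), (0.4 incongruent) -> mean(0.3, -0.4)
  expect_equal(bre$reinstatement[bre$block_id == 1], mean(c(0.3, -0.4)))
  expect_equal(bre$reinstatement[bre$block_id == 2], 0.5)
  expect_false(3 %in% bre$block_id)   # different-CTD pairs excluded
})

test_that("context-context tables enumerate unordered cross-run pairs", {
  sub <- quick_subject(seed = 12)
  ps <- exclude_events(sub$patterns$hippocampus, drop_run1 = FALSE)
  cc <- context_context_similarity(ps)
  expect_equal(nrow(cc), 48 * 40 / 2)   # 48 events, 40 out-of-run partners
  expect_true(all(cc$run_a != cc$run_b))
  expect_false(any(duplicated(t(apply(cc[c("event_a", "event_b")], 1,
                                      sort)))))
})

test_that("construction oracle: noise-free single-run correlations equal the
           planted targets", {
  np <- quick_neural(noise_sd = 0, hippo_fluct_sd = 0, hippo_amp_sd = 0,
                     gain_noise_sd = 0, gain_mean = 0, gain_hippo_fluct = 0,
                     gain_hippo_amp = 0,
                     rho_hippo_same_ctd = 0.07, rho_hippo_diff_ctd = 0.21,
                     rho_ctx_same_ctd = 0.05, rho_ctx_diff_ctd = 0.3)
  d <- generate_design(design_spec(n_runs = 1), seed = 13)
  ps <- generate_patterns(d, np, seed = 13)
  for (roi in c("cortical", "hippocampus")) {
    p <- ps[[roi]]
    ev <- p$events
    ci <- which(ev$class == "context_onset")
    same_ctd <- which(ev$ctd[ci[1]] == ev$ctd[ci] &
                        ev$context[ci] != ev$context[ci[1]])[1]
    diff_ctd <- which(ev$ctd[ci] != ev$ctd[ci[1]])[1]
    r_same <- stats::cor(p$pattern[ci[1], ], p$pattern[ci[same_ctd], ])
    r_diff <- stats::cor(p$pattern[ci[1], ], p$pattern[ci[diff_ctd], ])
    if (roi == "hippocampus") {
      expect_equal(r_same, 0.07, tolerance = 1e-6)
      expect_equal(r_diff, 0.21, tolerance = 1e-6)
    } else {
      expect_equal(r_same, 0.05, tolerance = 1e-6)
      expect_equal(r_diff, 0.3, tolerance = 1e-6)
    }
  }
})

test_that("planted correlation ordering reproduces in empirical
           condition means at low noise", {
  np <- quick_neural(noise_sd = 0.3, hippo_fluct_sd = 0,
                     rho_hippo_same_ctd = 0.02, rho_hippo_diff_ctd = 0.25)
  diffs <- vapply(1:5, function(i) {
    d <- generate_design(design_spec(), seed = 700 + i)
    ps <- generate_patterns(d, np, seed = 700 + i)
    cc <- context_context_similarity(ps$hippocampus)
    m <- cc_condition_means(cc)
    m$mean_z[m$relation == "same_ctd"] -
      m$mean_z[m$relation == "different_ctd"]
  }, 0)
  expect_true(all(diffs < 0))
})

test_that("non-PSD correlation targets raise a configuration error", {
  np <- quick_neural(rho_hippo_same_ctd = -0.9, rho_hippo_diff_ctd = 0.9,
                     rho_hippo_same_context = 0.9)
  d <- generate_design(design_spec(n_runs = 2), seed = 1)
  expect_error(generate_patterns(d, np, seed = 1),
               class = "ctdlearn_config_error")
})

test_that("differentiation tests detect the planted hippocampal structure", {
  np <- quick_neural()
  cc_all <- purrr::map_dfr(1:10, function(i) {
    sub <- quick_subject(seed = 800 + i, neural = np)
    cc <- context_context_similarity(sub$patterns$hippocampus)
    dplyr::mutate(cc, subject = i)
  })
  dt <- differentiation_tests(cc_all)
  val <- dt$tests[dt$tests$test == "validation_same_context_vs_different_ctd", ]
  dif <- dt$tests[dt$tests$test == "differentiation_same_ctd_vs_different_ctd", ]
  expect_gt(val$mean, 0)           # same context > different CTD
  expect_lt(dif$mean, 0)           # same CTD < different CTD after run 1
  expect_equal(val$runs, "1-6")
  expect_equal(dif$runs, "2-6")
  # run profile: same-CTD similarity declines from run 1 to runs 2-6
  rp <- dt$run_profile
  sctd <- rp[rp$relation == "same_ctd", ]
  expect_gt(sctd$mean_z[sctd$run == 1], mean(sctd$mean_z[sctd$run > 1]))
})

test_that("identical condition means flag the paired test", {
  res <- paired_t(c(1, 1, 1), c(1, 1, 1))
  expect_true(res$flagged)
})
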