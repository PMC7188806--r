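#' Specify a blocked context/task-demand design
#'
#' Describes the blocked experimental design in which four spatial contexts
#' are each probabilistically associated with one of two task demands
#' (face vs. object categorization). Defaults reproduce the standard session:
#' 6 runs of 8 blocks, 2 blocks per context per run, 8 trials per block with a
#' 75/25 split between the context's dominant task and the other task.
#'
#' Tasks are coded 0 (face) and 1 (object). The contextual task demand (CTD)
#' of a context is its dominant task; exactly half of the contexts must map to
#' each task demand.
#'
#' @param n_runs Number of scan runs.
#' @param n_blocks_per_run Blocks per run; must be a multiple of `n_contexts`.
#' @param n_trials_per_block Trials per block; `dominant_prob *
#'   n_trials_per_block` must be an integer so the contingency is realized
#'   exactly in every block.
#' @param n_contexts Number of spatial contexts (rooms).
#' @param dominant_prob Probability of the dominant task within a block.
#' @param ctd_assignment Integer vector of length `n_contexts` with values in
#'   \{0, 1\} giving each context's dominant task; defaults to the first half
#'   of contexts mapped to the face task (0), the rest to object (1).
#' @param timings Named list of event durations in seconds: `room` (pre-task
#'   room-interior period), `cue` (task cue), `stim` (stimulus), `iti`
#'   (inter-trial interval).
#' @return An object of class `design_spec`.
#' @export
#' @examples
#' design_spec()
design_spec <- function(n_runs = 6,
                        n_blocks_per_run = 8,
                        n_trials_per_block = 8,
                        n_contexts = 4,
                        dominant_prob = 0.75,
                        ctd_assignment = NULL,
                        timings = list(room = 7.75, cue = 0.25,
                                       stim = 1.5, iti = 4.25)) {
  counts <- c(n_runs = n_runs, n_blocks_per_run = n_blocks_per_run,
              n_trials_per_block = n_trials_per_block, n_contexts = n_contexts)
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      abort(sprintf("`%s` must be a positive integer", nm),
            class = "ctdlearn_config_error")
    }
  }
  stopifnot_scalar_prob(dominant_prob, "dominant_prob", open = TRUE)
  if (n_blocks_per_run %% n_contexts != 0) {
    abort("`n_blocks_per_run` must be a multiple of `n_contexts` so every context appears equally often per run",
          class = "ctdlearn_config_error")
  }
  n_dom <- dominant_prob * n_trials_per_block
  if (abs(n_dom - round(n_dom)) > 1e-9) {
    abort("`dominant_prob * n_trials_per_block` must be an integer so the contingency is realized exactly per block",
          class = "ctdlearn_config_error")
  }
  if (is.null(ctd_assignment)) {
    ctd_assignment <- rep(c(0L, 1L), each = n_contexts / 2)
  }
  if (length(ctd_assignment) != n_contexts ||
      !all(ctd_assignment %in% c(0L, 1L)) ||
      sum(ctd_assignment == 1L) != n_contexts / 2) {
    abort("`ctd_assignment` must assign exactly half the contexts to each task demand",
          class = "ctdlearn_config_error")
  }
  req <- c("room", "cue", "stim", "iti")
  if (!all(req %in% names(timings)) ||
      !all(vapply(timings[req], function(x) is.numeric(x) && x >= 0, TRUE))) {
    abort("`timings` must provide non-negative `room`, `cue`, `stim`, `iti` durations (seconds)",
          class = "ctdlearn_config_error")
  }
  structure(
    list(n_runs = as.integer(n_runs),
         n_blocks_per_run = as.integer(n_blocks_per_run),
         n_trials_per_block = as.integer(n_trials_per_block),
         n_contexts = as.integer(n_contexts),
         dominant_prob = dominant_prob,
         n_dominant = as.integer(round(n_dom)),
         ctd_assignment = as.integer(ctd_assignment),
         timings = timings[req]),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "<design_spec> %d runs x %d blocks x %d trials; %d contexts (%d/%d dominant/other trials per block)\n",
    x$n_runs, x$n_blocks_per_run, x$n_trials_per_block, x$n_contexts,
    x$n_dominant, x$n_trials_per_block - x$n_dominant))
  invisible(x)
}

#' Generate a randomized session design
#'
#' Lays out blocks and trials for one subject. Within each run every context
#' appears in `n_blocks_per_run / n_contexts` blocks, in a randomized order;
#' within each block exactly `dominant_prob * n_trials_per_block` trials
#' require the context's dominant task, in a randomized order. Timings place
#' the room-interior (context-onset) period at the start of each block,
#' followed by the trial cues.
#'
#' @param spec A [design_spec()].
#' @param seed Integer seed; identical seeds yield identical designs.
#' @return A `session_design`: list with `blocks` and `trials` tibbles.
#'   `blocks` has one row per block (`run`, `block`, `block_id`, `context`,
#'   `ctd`, `room_onset`); `trials` one row per trial, adding `trial`,
#'   `trial_id`, `task`, `congruent` and `cue_onset`. Onsets are in seconds,
#'   relative to run start.
#' @export
#' @examples
#' d <- generate_design(design_spec(), seed = 1)
#' dplyr::count(d$trials, context, congruent)
generate_design <- function(spec = design_spec(), seed = 1) {
  if (!inherits(spec, "design_spec")) spec <- do.call(design_spec, spec)
  tm <- spec$timings
  trial_step <- tm$cue + tm$stim + tm$iti
  block_len <- tm$room + spec$n_trials_per_block * trial_step

  with_seed(seed, {
    ctx <- unlist(lapply(seq_len(spec$n_runs), function(r) {
      sample(rep(seq_len(spec$n_contexts),
                 spec$n_blocks_per_run / spec$n_contexts))
    }))
    nb <- spec$n_runs * spec$n_blocks_per_run
    blk <- rep(seq_len(spec$n_blocks_per_run), spec$n_runs)
    blocks <- tibble::new_tibble(list(
      run = rep(seq_len(spec$n_runs), each = spec$n_blocks_per_run),
      block = blk,
      block_id = seq_len(nb),
      context = ctx,
      ctd = spec$ctd_assignment[ctx],
      room_onset = (blk - 1) * block_len), nrow = nb)

    ntb <- spec$n_trials_per_block
    # 6/2-style split realized exactly within every block, order randomized
    base <- c(rep(1L, spec$n_dominant), rep(0L, ntb - spec$n_dominant))
    dom <- vapply(seq_len(nb), function(i) sample(base), integer(ntb))
    bi <- rep(seq_len(nb), each = ntb)
    congr <- as.vector(dom == 1L)
    tasks <- as.integer(ifelse(congr, blocks$ctd[bi], 1L - blocks$ctd[bi]))
    tno <- rep(seq_len(ntb), nb)
    trials <- tibble::new_tibble(list(
      run = blocks$run[bi], block = blocks$block[bi], block_id = bi,
      context = blocks$context[bi], ctd = blocks$ctd[bi],
      trial = tno,
      task = tasks,
      congruent = congr,
      cue_onset = blocks$room_onset[bi] + tm$room + (tno - 1) * trial_step,
      trial_id = seq_len(nb * ntb)), nrow = nb * ntb)

    structure(list(blocks = blocks[, c("run", "block", "block_id", "context",
                                       "ctd", "room_onset")],
                   trials = trials, spec = spec, seed = seed),
              class = "session_design")
  })
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("<session_design> %d blocks, %d trials (seed %s)\n",
              nrow(x$blocks), nrow(x$trials), format(x$seed)))
  invisible(x)
}

#' Write session events as a BIDS-style events table
#'
#' One row per event (context onset and trial cue), with `onset` and
#' `duration` in seconds, 0-based `run` and `block` indices, and RT in ms.
#' A sidecar JSON describing the columns is written next to the TSV.
#'
#' @param design A `session_design`.
#' @param behavior Optional behavior tibble from [generate_behavior()]; adds
#'   `accuracy`, `rt_ms` and `post_error` columns for trial events.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(design, path, behavior = NULL) {
  tm <- design$spec$timings
  ctx <- dplyr::transmute(design$blocks,
    onset = .data$room_onset, duration = tm$room,
    run = .data$run - 1L, block = .data$block - 1L,
    context = .data$context, trial_type = "context_onset",
    task = NA_integer_, accuracy = NA_integer_, rt_ms = NA_real_,
    post_error = NA)
  tr <- if (is.null(behavior)) design$trials else behavior
  trl <- dplyr::transmute(tr,
    onset = .data$cue_onset, duration = tm$cue,
    run = .data$run - 1L, block = .data$block - 1L,
    context = .data$context, trial_type = "trial_cue",
    task = .data$task,
    accuracy = if ("accuracy" %in% names(tr)) .data$accuracy else NA_integer_,
    rt_ms = if ("rt_ms" %in% names(tr)) .data$rt_ms else NA_real_,
    post_error = if ("post_error" %in% names(tr)) .data$post_error else NA)
  ev <- dplyr::arrange(dplyr::bind_rows(ctx, trl), .data$run, .data$onset)
  readr::write_tsv(ev, path)
  sidecar <- list(
    onset = "event onset in seconds, relative to run start",
    duration = "event duration in seconds",
    run = "0-based run index", block = "0-based block index within run",
    context = "1-based context (room) id",
    trial_type = "context_onset (room interior) or trial_cue",
    task = "0 = face, 1 = object", accuracy = "1 = correct",
    rt_ms = "response time in milliseconds",
    post_error = "trial immediately follows an error trial")
  jsonlite::write_json(sidecar, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
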