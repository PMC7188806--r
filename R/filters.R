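#' Flag trials for inclusion in the RT analyses
#'
#' Applies the three exclusion rules: error trials, trials immediately
#' following an error (post-error slowing is a separate process), and trials
#' whose RT exceeds the subject's median by more than `sd_mult` standard
#' deviations. The median and SD are computed over the correct, non-post-error
#' trials, and the RT rule is one-sided (only unusually *long* RTs are
#' removed). When several rules apply, the recorded reason follows the order
#' error > post_error > rt_outlier.
#'
#' @param behavior Trial tibble with `accuracy`, `post_error` and `rt_ms`.
#' @param sd_mult RT-outlier multiplier (default 2.5; `Inf` disables the RT
#'   rule).
#' @return `behavior` with logical `included` and character `reason`
#'   (`NA` for included trials) columns; exclusion counts per reason are
#'   attached as attribute `"filter_counts"`.
#' @export
#' @examples
#' d <- generate_design(design_spec(n_runs = 1), seed = 1)
#' b <- generate_behavior(d, generative_params(), seed = 1)
#' f <- filter_trials(b)
#' attr(f, "filter_counts")
filter_trials <- function(behavior, sd_mult = 2.5) {
  need <- c("accuracy", "post_error", "rt_ms")
  if (!all(need %in% names(behavior))) {
    abort(sprintf("`behavior` must contain %s", paste(need, collapse = ", ")),
          class = "ctdlearn_domain_error")
  }
  err <- behavior$accuracy == 0
  post <- behavior$post_error & !err
  base <- !err & !behavior$post_error
  if (!any(base)) {
    abort("all trials are error or post-error trials", class = "ctdlearn_degenerate_error")
  }
  med <- median(behavior$rt_ms[base])
  s <- sd(behavior$rt_ms[base])
  if (is.na(s)) s <- 0
  thr <- if (is.infinite(sd_mult)) Inf else med + sd_mult * s
  out_rt <- base & behavior$rt_ms > thr
  reason <- dplyr::case_when(err ~ "error",
                             post ~ "post_error",
                             out_rt ~ "rt_outlier",
                             TRUE ~ NA_character_)
  behavior$included <- is.na(reason)
  behavior$reason <- reason
  if (!any(behavior$included)) {
    abort("all trials excluded", class = "ctdlearn_degenerate_error")
  }
  attr(behavior, "filter_counts") <-
    c(error = sum(err), post_error = sum(post), rt_outlier = sum(out_rt),
      included = sum(behavior$included))
  behavior
}

#' Z-score predictors over the included trials
#'
#' Normalizes the named columns to mean 0 and unit sample SD, computed over
#' (and applied to) the included trials only. Excluded trials keep `NA` in
#' the normalized columns, which guarantees they cannot leak into fits.
#'
#' @param behavior Output of [filter_trials()].
#' @param vars Columns to normalize.
#' @param suffix Suffix for the new columns.
#' @return `behavior` with added `<var><suffix>` columns.
#' @export
normalize_predictors <- function(behavior, vars = c("pe_temporal",
                                                    "pe_contextual"),
                                 suffix = "_z") {
  incl <- behavior$included %||% rep(TRUE, nrow(behavior))
  for (v in vars) {
    z <- rep(NA_real_, nrow(behavior))
    z[incl] <- zscore(behavior[[v]][incl], name = v)
    behavior[[paste0(v, suffix)]] <- z
  }
  behavior
}
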