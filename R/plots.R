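#' @method autoplot ctd_quintiles
#' @export
autoplot.ctd_quintiles <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::labs(x = paste("quintile of", attr(object, "pe")),
                  y = paste("mean", attr(object, "outcome")),
                  title = "Outcome by prediction-error quintile") +
    ggplot2::theme_minimal()
}

#' Plot factorial similarity cell means
#'
#' Bar-style display of the 3 x 2 condition cells (context relation by
#' congruency) of context-trial pattern similarity, either for one subject's
#' [cell_means()] or for a stacked table with a `subject` column (group
#' mean +/- SEM).
#'
#' @param cells Tibble with `relation`, `congruency`, `mean_z` (optionally
#'   `subject`).
#' @return A ggplot object.
#' @export
plot_cell_means <- function(cells) {
  df <- if ("subject" %in% names(cells)) {
    cells |>
      dplyr::group_by(.data$relation, .data$congruency) |>
      dplyr::summarise(sem = sd(.data$mean_z) / sqrt(dplyr::n()),
                       mean_z = mean(.data$mean_z), .groups = "drop")
  } else dplyr::mutate(cells, sem = NA_real_)
  df$relation <- factor(df$relation, levels = relation_levels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$relation, y = .data$mean_z,
                                   fill = .data$congruency)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_z - .data$sem,
                   ymax = .data$mean_z + .data$sem),
      position = ggplot2::position_dodge(0.8), width = 0.2, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "context-trial similarity (Fisher z)",
                  title = "CTD reinstatement: condition cells") +
    ggplot2::theme_minimal()
}

#' @method autoplot ctd_differentiation
#' @export
autoplot.ctd_differentiation <- function(object, ...) {
  ggplot2::ggplot(object$run_profile,
                  ggplot2::aes(x = .data$run, y = .data$mean_z,
                               colour = .data$relation)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "run", y = "context-context similarity (Fisher z)",
                  title = "Hippocampal pattern similarity across runs") +
    ggplot2::theme_minimal()
}

#' Plot group coefficients with standard errors
#'
#' Dot-and-whisker display of a [group_inference()] table.
#'
#' @param stats A `ctd_group_stats` tibble.
#' @return A ggplot object.
#' @export
plot_group_coefficients <- function(stats) {
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$mean, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$mean - .data$sem,
                                          xmax = .data$mean + .data$sem)) +
    ggplot2::labs(x = "group mean coefficient (+/- SEM)", y = NULL) +
    ggplot2::theme_minimal()
}
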