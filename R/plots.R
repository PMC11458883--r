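#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a survival curve
#'
#' @param object A [survival_curve()].
#' @param horizon Upper time limit (years). Default 10.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot survival_curve
#' @export
autoplot.survival_curve <- function(object, horizon = 10, ...) {
  tm <- seq(0, horizon, length.out = 400)
  df <- tibble::tibble(time_years = tm, survival = surv_prob(object, tm))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_years, .data$survival)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time (years)", y = "S(t)",
                  title = format(object)) +
    ggplot2::theme_minimal()
}

#' Plot state occupancy over time for a cohort trace
#'
#' Stacked area chart of progression-free occupancy by line, any
#' post-progression occupancy, and death.
#'
#' @param object A `cohort_trace` from [simulate_sequence()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cohort_trace
#' @export
autoplot.cohort_trace <- function(object, ...) {
  K <- attr(object, "n_lines")
  cols <- c(paste0("pf_line", seq_len(K)), "post_progression", "dead")
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = dplyr::all_of(cols),
                              names_to = "state", values_to = "fraction")
  long$state <- factor(long$state, levels = rev(cols))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_years, .data$fraction,
                                     fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Time (years)", y = "Cohort fraction",
                  fill = "State", title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Compare per-line progression-free time across sequences
#'
#' Stacked bars of per-line expected progression-free years (total bar
#' height is overall survival in terminal-death mode).
#'
#' @param outcomes A list of `sequence_outcomes`.
#' @return A ggplot.
#' @export
plot_sequence_comparison <- function(outcomes) {
  if (inherits(outcomes, "sequence_outcomes")) outcomes <- list(outcomes)
  df <- purrr::map_dfr(outcomes, tidy)
  df$line <- factor(df$line, levels = rev(sort(unique(df$line))))
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$pfs_years,
                                   fill = .data$line)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Expected progression-free years",
                  fill = "Line") +
    ggplot2::theme_minimal()
}
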