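#' Plot cohort-mean Shift Index by condition
#'
#' Mean SI per condition, one line per series: the X series (1600-Hz high
#' cutoff) and the Y series (1300-Hz). An upward trend across the low-cut
#' index and a Y line above the X line are the two qualitative signatures
#' of spectral listening under simulated hearing loss.
#'
#' @param summary An `si_summary` tibble from [cohort_summary()].
#'
#' @return A ggplot object.
#'
#' @export
plot_si_summary <- function(summary) {
  d <- decorate_summary(summary)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$low_cut, y = .data$mean_si,
                                  colour = .data$series,
                                  shape = .data$series)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_x_continuous(breaks = c(250, 500, 750, 1000)) +
    ggplot2::scale_colour_manual(values = c(X = "firebrick", Y = "steelblue")) +
    ggplot2::labs(x = "Low-frequency elimination cutoff (Hz)",
                  y = "Mean Shift Index",
                  colour = "Series", shape = "Series") +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
}

#' Plot the response breakdown by condition
#'
#' Percentages of ambiguous, unambiguous-spectral and unambiguous-F0
#' responses per condition.
#'
#' @param summary An `si_summary` tibble from [cohort_summary()].
#'
#' @return A ggplot object.
#'
#' @export
plot_response_breakdown <- function(summary) {
  d <- decorate_summary(summary) |>
    tidyr::pivot_longer(c("pct_ambiguous", "pct_spectral", "pct_f0"),
                        names_to = "kind", values_to = "pct") |>
    dplyr::mutate(kind = dplyr::recode(.data$kind,
      pct_ambiguous = "ambiguous", pct_spectral = "spectral (SI = +1)",
      pct_f0 = "F0 (SI = -1)"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$pct,
                                  fill = .data$kind)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "Participants (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_si_summary
#' @param object An `si_summary` tibble.
#' @param ... Unused.
#' @export
autoplot.si_summary <- function(object, ...) plot_si_summary(object)

decorate_summary <- function(summary) {
  stopifnot(is.data.frame(summary), "condition" %in% names(summary))
  summary |>
    dplyr::mutate(
      series = substr(.data$condition, 1L, 1L),
      low_cut = c(250, 500, 750, 1000)[
        as.integer(substr(.data$condition, 2L, 2L))]
    )
}
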