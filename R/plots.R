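#' Plot the cumulative-contribution curves and knee cutoffs
#'
#' One panel per segment class: cumulative fraction of the total ddG
#' against rank, the chord used by the knee rule, and a vertical line at
#' the selected cutoff.
#'
#' @param calls a `mirsnp_calls` tibble from [select_inflection()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_cumulative_fraction <- function(calls, ...) {
  knees <- calls |>
    dplyr::group_by(.data$segment_class) |>
    dplyr::summarise(knee = sum(.data$candidate), .groups = "drop")
  ggplot2::ggplot(calls, ggplot2::aes(.data$rank, .data$cumulative_fraction)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_vline(
      data = knees, ggplot2::aes(xintercept = .data$knee),
      linetype = "dashed", color = "firebrick"
    ) +
    ggplot2::facet_wrap(~segment_class, scales = "free_x") +
    ggplot2::labs(
      x = "rank by |ddG|", y = "cumulative fraction of total ddG",
      title = "Inflection-point candidate cutoff"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_cumulative_fraction
#' @param object a `mirsnp_calls` tibble.
#' @export
autoplot.mirsnp_calls <- function(object, ...) plot_cumulative_fraction(object, ...)

#' Plot burden selection frequencies
#'
#' Selection frequency across resampling rounds for every candidate,
#' ordered within segment class, with the burden threshold `1 - alpha`.
#'
#' @param burden a `mirsnp_burden` tibble from [monte_carlo_burden()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_selection_frequency <- function(burden, ...) {
  alpha <- attr(burden, "alpha") %||% 0.05
  d <- burden |>
    dplyr::group_by(.data$segment_class) |>
    dplyr::arrange(dplyr::desc(.data$selection_frequency), .by_group = TRUE) |>
    dplyr::mutate(idx = dplyr::row_number()) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(.data$idx, .data$selection_frequency,
    color = .data$burden
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1 - alpha, linetype = "dashed") +
    ggplot2::facet_wrap(~segment_class, scales = "free_x") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey50")) +
    ggplot2::labs(
      x = "candidate (ordered)", y = "selection frequency",
      title = "Monte-Carlo burden selection stability"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_selection_frequency
#' @param object a `mirsnp_burden` tibble.
#' @export
autoplot.mirsnp_burden <- function(object, ...) plot_selection_frequency(object, ...)
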