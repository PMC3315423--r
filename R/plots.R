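#' Plot reliabilities against the grading bands
#'
#' Bar chart of between-visit and between-centre reliabilities per
#' measure, with horizontal reference lines at the poor/moderate (0.50),
#' moderate/good (0.70) and good/excellent (0.90) cut points.
#'
#' @param data A tibble with columns `measure`, `factor` and `value`
#'   (e.g. the `reliability` element produced by
#'   [run_reliability_report()], or stacked [reliability_pair()] rows).
#' @return A ggplot object.
#' @export
plot_reliability <- function(data) {
  ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data$measure, y = .data$value, fill = .data$factor)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_hline(
      yintercept = c(0.5, 0.7, 0.9),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "Reliability",
      fill = "Between-", title = "Scanner-related reliability by measure"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname estimate_variance_components
#' @param object A `morph_varcomp` object.
#' @export
autoplot.morph_varcomp <- function(object, ...) {
  tab <- object$components |>
    dplyr::mutate(share = .data$variance / sum(.data$variance))
  ggplot2::ggplot(
    tab,
    ggplot2::aes(
      x = stats::reorder(.data$term, .data$share),
      y = .data$share
    )
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Share of total variance",
      title = "Variance components"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname sulcal_reliability_summary
#' @param object A `morph_sulcal_summary` object.
#' @param ... Unused.
#' @export
autoplot.morph_sulcal_summary <- function(object, ...) {
  ggplot2::ggplot(
    object$per_sulcus,
    ggplot2::aes(x = .data$factor, y = .data$value)
  ) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_hline(
      yintercept = c(0.5, 0.7, 0.9),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(
      x = NULL, y = "Reliability",
      title = sprintf(
        "Per-sulcus reliabilities: %s (%s)", object$measure, object$algorithm
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
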