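#' Plot estimated response curves per quantifier
#'
#' Draws each participant's posterior-mean response curve (thin gray) and
#' the curve at the quantifier's mean parameters (colored, bold) over the
#' presented-percentage range. Negative quantifiers are shown on the raw
#' (decreasing) scale so the panels read like the raw data.
#'
#' @param object A `quantfit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quantfit <- function(object, ...) {
  pm <- posterior_means(object)
  grid <- tidyr::expand_grid(pm, percent = seq(1, 99, by = 2)) |>
    dplyr::filter(.data$percent != 50) |>
    dplyr::mutate(
      prob = response_probability(center_percent(.data$percent),
                                  .data$beta, .data$alpha, .data$gamma),
      prob = dplyr::if_else(.data$quantifier %in% negative_quantifiers(),
                            1 - .data$prob, .data$prob))
  mean_curve <- grid |>
    dplyr::group_by(.data$quantifier, .data$percent) |>
    dplyr::summarise(prob = mean(.data$prob), .groups = "drop")
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$percent, y = .data$prob)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant_id),
                       color = "gray70", linewidth = 0.3, alpha = 0.6) +
    ggplot2::geom_line(data = mean_curve, ggplot2::aes(color = .data$quantifier),
                       linewidth = 1.1) +
    ggplot2::facet_wrap(~quantifier) +
    ggplot2::labs(x = "Presented percentage", y = "P(judged true)") +
    ggplot2::guides(color = "none") +
    ggplot2::theme_minimal()
}

#' Plot cluster-mean threshold profiles
#'
#' One line per cluster across quantifiers, on the percent scale, with
#' ribbons of +/- 1 within-cluster SD.
#'
#' @param object A `quant_clusters`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quant_clusters <- function(object, ...) {
  s <- object$summary |>
    dplyr::mutate(quantifier = factor(.data$quantifier, quantifier_levels()),
                  cluster = factor(.data$cluster))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$quantifier, y = .data$percent,
                                  color = .data$cluster, group = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = threshold_to_percent(.data$mean - .data$sd),
      ymax = threshold_to_percent(.data$mean + .data$sd))) +
    ggplot2::labs(x = NULL, y = "Threshold (percent scale)", color = "Cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot per-participant threshold differences
#'
#' Dot-and-interval plot of posterior threshold differences (from
#' [threshold_differences()]), participants in the order given by the
#' `order_value` column, optionally colored by cluster membership.
#'
#' @param differences Tibble from [threshold_differences()].
#' @param clusters Optional `quant_clusters` for coloring.
#' @param label Y-axis label.
#' @return A ggplot object.
#' @export
plot_threshold_differences <- function(differences, clusters = NULL,
                                       label = "Threshold difference") {
  d <- dplyr::mutate(differences,
                     participant_id = factor(.data$participant_id,
                                             levels = .data$participant_id))
  if (!is.null(clusters)) {
    d <- dplyr::left_join(d, clusters$assignments, by = "participant_id") |>
      dplyr::mutate(cluster = factor(.data$cluster))
    mapping <- ggplot2::aes(x = .data$participant_id, y = .data$difference,
                            ymin = .data$lower, ymax = .data$upper,
                            colour = .data$cluster)
  } else {
    mapping <- ggplot2::aes(x = .data$participant_id, y = .data$difference,
                            ymin = .data$lower, ymax = .data$upper)
  }
  ggplot2::ggplot(d, mapping) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "gray50") +
    ggplot2::geom_pointrange(size = 0.2) +
    ggplot2::labs(x = "Participant (ordered)", y = label,
                  color = if (!is.null(clusters)) "Cluster" else NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
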