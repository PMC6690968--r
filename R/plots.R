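#' Plot a binned measure-essentiality correlation
#'
#' Per-bin fraction of essential genes against the bin's mean measure value.
#'
#' @param object A `binned_correlation`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.binned_correlation <- function(object, ...) {
  ggplot2::ggplot(object$bins, ggplot2::aes(x = .data$mean_value, y = .data$f_E)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.4) +
    ggplot2::labs(
      x = "mean measure value (per bin)",
      y = expression(f[E] ~ "(fraction essential)"),
      subtitle = sprintf("Pearson R = %.3f, p = %.2g", object$R, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a pruning curve of excess clustering
#'
#' Excess clustering against the fraction of removed nodes, with a +/- 3
#' sigma band from the per-step null spread. Supply the random reference
#' from [random_pruning_band()] via `reference` to draw the comparison.
#'
#' @param object A `pruning_curve`.
#' @param reference Optional reference `pruning_curve` (drawn in grey).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.pruning_curve <- function(object, reference = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$f, y = .data$delta_c)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$delta_c - 3 * .data$sigma,
        ymax = .data$delta_c + 3 * .data$sigma
      ),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "f (fraction of nodes removed)",
      y = expression(Delta * C ~ "(excess clustering)")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(reference)) {
    p <- p + ggplot2::geom_line(
      data = reference, colour = "grey50", linetype = 2
    )
  }
  p
}

#' Plot an essential-gene classification in the (k, w) plane
#'
#' Degree against link-clustering score on a log-degree axis, coloured by
#' class, with the MCC-optimal cutoffs drawn as dashed lines.
#'
#' @param object An `eg_classification`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.eg_classification <- function(object, ...) {
  ggplot2::ggplot(
    object$nodes,
    ggplot2::aes(x = .data$k, y = .data$w, colour = .data$class)
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = object$k_c, linetype = 2, colour = "grey40") +
    ggplot2::geom_hline(yintercept = object$w_c, linetype = 2, colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(
      "k-dependent" = "#d73027", "w-dependent" = "#4575b4",
      "unclassified-EG" = "#fdae61", "non-EG" = "grey70"
    )) +
    ggplot2::labs(x = "k (degree)", y = "w (link clustering)") +
    ggplot2::theme_minimal()
}

#' Plot group link-density impact across hierarchy levels
#'
#' Mean per-class community link-density change upon single-node removal,
#' by hierarchy fraction, with standard-error ribbons.
#'
#' @param dd A tibble from [group_delta_density()].
#' @return A ggplot object.
#' @export
plot_group_delta_density <- function(dd) {
  dd <- dd[!is.na(dd$mean_delta_d), ]
  ggplot2::ggplot(
    dd,
    ggplot2::aes(x = .data$f_H, y = .data$mean_delta_d, colour = .data$class)
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_delta_d - .data$se,
        ymax = .data$mean_delta_d + .data$se,
        fill = .data$class
      ),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = expression(f[H] ~ "(hierarchy fraction)"),
      y = expression(Delta * D ~ "(link-density change)")
    ) +
    ggplot2::theme_minimal()
}
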