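#' Plot an amplicon tiling path
#'
#' Draws the selected amplicons as horizontal bars along the target
#' coordinate, one lane per multiplex group, with uncovered gaps shaded.
#'
#' @param object A `tiling_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tiling_result
#' @export
autoplot.tiling_result <- function(object, ...) {
  path <- object$path
  path$lane <- as.integer(factor(path$group %||% "A"))
  gaps <- object$gaps
  gg <- ggplot2::ggplot(path)
  if (nrow(gaps) > 0) {
    gg <- gg + ggplot2::geom_rect(
      data = gaps,
      ggplot2::aes(
        xmin = .data$start, xmax = .data$stop,
        ymin = -Inf, ymax = Inf
      ),
      fill = "grey85", inherit.aes = FALSE
    )
  }
  gg +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$amplicon_start, xend = .data$amplicon_stop,
        y = .data$group, yend = .data$group, colour = .data$group
      ),
      linewidth = 4, lineend = "butt"
    ) +
    ggplot2::labs(
      x = sprintf(
        "position (target %d-%d, coverage %.1f%%)",
        object$target[1], object$target[2],
        100 * object$coverage_fraction
      ),
      y = "multiplex group",
      title = "Minimum amplicon tiling path"
    ) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-primer specificity margins
#'
#' On-target Tm against the maximum misprime Tm for every scanned primer,
#' with the specificity margin drawn as a reference line: primers above the
#' line (margin or more above their worst off-target site) pass.
#'
#' @param profiles Misprime profile tibble from [misprime_profile()].
#' @param threshold_celsius Margin to draw (default 10).
#' @return A ggplot object.
#' @export
plot_specificity <- function(profiles, threshold_celsius = 10) {
  shown <- dplyr::filter(profiles, is.finite(.data$tm_offtarget_max))
  ggplot2::ggplot(
    shown,
    ggplot2::aes(
      x = .data$tm_offtarget_max, y = .data$tm_on_target,
      colour = .data$pass_specificity
    )
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(
      intercept = threshold_celsius, slope = 1,
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "maximum misprime Tm (deg C)",
      y = "on-target Tm (deg C)",
      colour = "passes margin",
      title = "Priming specificity margins"
    ) +
    ggplot2::theme_minimal()
}
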