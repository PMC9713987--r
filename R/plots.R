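needs_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the 'ggplot2' package", call. = FALSE)
  }
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param psa a `psa_result` from [run_psa()].
#' @param threshold optional willingness-to-pay marker (euro/QALY).
#' @return A ggplot object.
#' @export
plot_ceac <- function(psa, threshold = 30000) {
  needs_ggplot2()
  ggplot2::ggplot(psa$ceac, ggplot2::aes(x = lambda, y = p_intervention)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed", colour = "grey40") +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(
      x = "Willingness to pay (EUR/QALY)",
      y = sprintf("P(%s cost-effective)", psa$arms[2]),
      title = "Cost-effectiveness acceptability curve"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the incremental cost-effectiveness plane
#'
#' @param psa a `psa_result`.
#' @param threshold willingness-to-pay ray to draw (euro/QALY).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, threshold = 30000) {
  needs_ggplot2()
  ggplot2::ggplot(psa$draws, ggplot2::aes(x = delta_qaly, y = delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6, colour = "#2166ac") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::geom_abline(slope = threshold, intercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = sprintf("Incremental QALYs (%s - %s)", psa$arms[2], psa$arms[1]),
      y = "Incremental cost (EUR)",
      title = "Incremental cost-effectiveness plane"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#'
#' @param torn data frame from [tornado()].
#' @param base_ratio reference-case cost-per-QALY ratio to centre bars on.
#' @return A ggplot object.
#' @export
plot_tornado <- function(torn, base_ratio = NULL) {
  needs_ggplot2()
  torn$parameter <- factor(torn$parameter, levels = rev(torn$parameter))
  p <- ggplot2::ggplot(torn, ggplot2::aes(y = parameter)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = ratio_low, xend = ratio_high, yend = parameter),
      linewidth = 5, colour = "#2166ac", alpha = 0.8
    ) +
    ggplot2::labs(
      x = "Cost per QALY (EUR/QALY, signed ratio)",
      y = NULL, title = "One-way sensitivity (tornado)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(base_ratio)) {
    p <- p + ggplot2::geom_vline(xintercept = base_ratio, linetype = "dashed", colour = "grey40")
  }
  p
}
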