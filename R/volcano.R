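#' Volcano plot of a disproportionality screen
#'
#' Scatter of effect size (`ln ROR`) against significance (`-log10 p`), one
#' point per exposure, colored blue-to-red by the number of event reports,
#' with the significance baseline drawn as a red horizontal line (p = 0.05 at
#' y = 1.301 by default). Exposures with an undefined ROR have no x
#' coordinate and are dropped from the plot (with how many noted in the
#' subtitle when any).
#'
#' @param results Screen results from [screen_exposures()].
#' @param p_baseline Significance baseline to draw (default 0.05).
#' @param title Optional plot title.
#' @param label_signals Annotate signal points with their exposure label
#'   (default `FALSE`).
#' @return A ggplot object.
#' @export
volcano_plot <- function(results, p_baseline = 0.05, title = NULL,
                         label_signals = FALSE) {
  plotted <- dplyr::filter(results, is.finite(.data$ln_ror))
  dropped <- nrow(results) - nrow(plotted)
  p <- ggplot2::ggplot(
    plotted,
    ggplot2::aes(x = .data$ln_ror, y = .data$neg_log10_p,
                 colour = .data$n_event_reports)
  ) +
    ggplot2::geom_hline(yintercept = -log10(p_baseline), colour = "red") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_gradient(low = "blue", high = "red",
                                   name = "event reports") +
    ggplot2::labs(
      x = "ln ROR", y = expression(-log[10] * italic(P)),
      title = title,
      subtitle = if (dropped > 0) {
        sprintf("%d exposure(s) with undefined ROR not shown", dropped)
      }
    ) +
    ggplot2::theme_minimal()
  if (label_signals && any(plotted$is_signal)) {
    p <- p + ggplot2::geom_text(
      data = dplyr::filter(plotted, .data$is_signal),
      ggplot2::aes(label = .data$exposure),
      vjust = -0.6, size = 3, show.legend = FALSE
    )
  }
  p
}
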