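evidence_band_layers <- function() {
  bounds <- log10(c(1, 3, 10, 30, 100))
  labels <- c("anecdotal", "moderate", "strong", "very strong", "extreme")
  list(
    ggplot2::geom_hline(
      yintercept = bounds,
      linetype = "dashed", colour = "grey70", linewidth = 0.3
    ),
    ggplot2::annotate(
      "text",
      x = Inf, y = bounds + 0.02, label = labels,
      hjust = 1.05, vjust = 0, size = 2.8, colour = "grey40"
    )
  )
}

#' Evidence for the null against the p-value
#'
#' Scatterplot of log10 BF01 against the study p-value with the Jeffreys
#' category bands marked — the view that shows how weakly a nonsignificant
#' p-value predicts the strength of evidence for the null.
#'
#' @param reanalysis A per-study table from [reanalyze()].
#' @param p_value Which p-value goes on the x axis (`"uncorrected"` or
#'   `"yates"`).
#' @return A ggplot object.
#' @export
plot_evidence_vs_p <- function(reanalysis, p_value = c("uncorrected", "yates")) {
  p_value <- match.arg(p_value)
  xcol <- if (p_value == "uncorrected") "p_uncorrected" else "p_yates"
  ggplot2::ggplot(
    reanalysis,
    ggplot2::aes(x = .data[[xcol]], y = .data$log10_bf01)
  ) +
    evidence_band_layers() +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("p-value (%s)", p_value),
      y = expression(log[10] ~ BF[0][1]),
      title = "Strength of evidence for the null vs p-value"
    ) +
    ggplot2::theme_minimal()
}

#' Evidence for the null against total sample size
#'
#' Scatterplot of log10 BF01 against log10 total sample size with a least
#' squares trend — the view that shows larger trials delivering more
#' compelling evidence of absence.
#'
#' @inheritParams plot_evidence_vs_p
#' @return A ggplot object.
#' @export
plot_evidence_vs_n <- function(reanalysis) {
  ggplot2::ggplot(
    reanalysis,
    ggplot2::aes(x = log10(.data$n_total), y = .data$log10_bf01)
  ) +
    evidence_band_layers() +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.5) +
    ggplot2::labs(
      x = expression(log[10] ~ "total sample size"),
      y = expression(log[10] ~ BF[0][1]),
      title = "Strength of evidence for the null vs sample size"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a corpus reanalysis
#'
#' Dispatches to [plot_evidence_vs_p()] (`type = "p"`) or
#' [plot_evidence_vs_n()] (`type = "n"`).
#'
#' @param object A `corpus_reanalysis` tibble.
#' @param type `"p"` or `"n"`.
#' @param ... Passed on to the plot function.
#' @method autoplot corpus_reanalysis
#' @export
#' @importFrom ggplot2 autoplot
autoplot.corpus_reanalysis <- function(object, type = c("p", "n"), ...) {
  type <- match.arg(type)
  if (type == "p") plot_evidence_vs_p(object, ...) else plot_evidence_vs_n(object)
}
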