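#' Plot completeness or concordance against a locus attribute
#'
#' Raw bin means are drawn as points with the smoothed series as a line,
#' the usual way read-length or unit-size effects on call quality are
#' inspected.
#'
#' @param bins tibble from [bin_metrics()] (optionally with extra grouping
#'   columns, mapped to colour via `colour`).
#' @param metric "completeness" or "concordance".
#' @param colour optional column name mapped to colour.
#' @return a ggplot object.
#' @export
plot_metric_by_bin <- function(bins, metric = c("concordance",
                                                "completeness"),
                               colour = NULL) {
  metric <- match.arg(metric)
  smooth_col <- paste0(metric, "_smooth")
  aes_pt <- if (is.null(colour)) {
    ggplot2::aes(x = .data$bin, y = .data[[metric]])
  } else {
    ggplot2::aes(x = .data$bin, y = .data[[metric]],
                 colour = .data[[colour]])
  }
  ggplot2::ggplot(bins, aes_pt) +
    ggplot2::geom_point(alpha = 0.5, size = 0.9) +
    ggplot2::geom_line(ggplot2::aes(y = .data[[smooth_col]])) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "reference repeat length (bases)", y = metric) +
    ggplot2::theme_minimal()
}

#' Plot percent in-phase variation by repeat length
#'
#' @param phase tibble from [in_phase_analysis()].
#' @return a ggplot object.
#' @export
plot_in_phase <- function(phase) {
  ggplot2::ggplot(phase, ggplot2::aes(
    x = .data$length_bin, y = .data$percent_in_phase,
    colour = factor(.data$unit_length))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "modal allele length (bases)",
                  y = "% in-phase (whole-unit) variants",
                  colour = "unit size") +
    ggplot2::theme_minimal()
}

#' Plot unit-delta histograms per unit size
#'
#' Mass away from integer positions flags non-stepwise variation (e.g. the
#' half-unit signature of 2-base events in tetranucleotides).
#'
#' @param hist tibble from [unit_delta_histogram()].
#' @return a ggplot object.
#' @export
plot_unit_deltas <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$delta_units,
                                     y = .data$freq)) +
    ggplot2::geom_col(width = 0.12) +
    ggplot2::facet_wrap(~unit_length, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "allele difference from modal (repeat units)",
                  y = "frequency") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a read-length bias bootstrap result
#'
#' Per-group frequency of allele-length difference from the reference at
#' discordant loci, with the bootstrap percentile bands as error bars.
#'
#' @param object an `msat_bias_test`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.msat_bias_test <- function(object, ...) {
  ggplot2::ggplot(object$bands, ggplot2::aes(
    x = .data$delta, y = .data$freq, fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::labs(x = "allele length - reference length (bases)",
                  y = "frequency of discordant loci",
                  fill = "read-length group") +
    ggplot2::theme_minimal()
}
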