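# ggplot2 visualisations of barcode-gap structure.

#' Barcode-gap scatter plot
#'
#' Maximum intra-specific distance against nearest-neighbour distance per
#' species; points below the 1:1 line show a barcode gap.
#'
#' @param summaries Output of [species_summaries()] (optionally with a `loci`
#'   column, used for facetting).
#' @return A ggplot object.
#' @export
plot_barcode_gap <- function(summaries) {
  p <- ggplot2::ggplot(summaries,
                       ggplot2::aes(x = .data$nn_distance,
                                    y = .data$max_intra,
                                    colour = .data$species)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "Distance to nearest neighbour (K2P %)",
                  y = "Maximum intra-specific distance (K2P %)") +
    ggplot2::theme_minimal()
  if ("loci" %in% names(summaries))
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$loci))
  p
}

#' Intra- vs inter-specific distance histogram
#'
#' @param hist_data Output of [distance_histogram()].
#' @return A ggplot object.
#' @export
plot_distance_histogram <- function(hist_data) {
  ggplot2::ggplot(hist_data,
                  ggplot2::aes(x = 100 * (.data$bin_start + .data$bin_end) / 2,
                               y = .data$count, fill = .data$series)) +
    ggplot2::geom_col(position = "dodge",
                      width = 100 * (hist_data$bin_end[1] - hist_data$bin_start[1])) +
    ggplot2::labs(x = "K2P distance (%)", y = "Number of pairs",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
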