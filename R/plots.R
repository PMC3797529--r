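#' Plot the per-position discrimination of a profile
#'
#' Shows the consensus emission score (the best attainable score per match
#' position) along the model; flat stretches near zero indicate weakly
#' constrained positions.
#'
#' @param object A `sat_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sat_profile <- function(object, ...) {
  tb <- generics::tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$position, y = .data$best_score)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "match position", y = "consensus emission (bits)") +
    ggplot2::theme_minimal()
}

#' Map annotated units along the chromosomes
#'
#' @param units Unit tibble (needs `seq_id`, `start`, `end`; an `arm`
#'   column colours the units).
#' @param centromeres Optional centromere tibble drawn as grey boxes.
#' @return A ggplot.
#' @export
plot_unit_map <- function(units, centromeres = NULL) {
  units <- tibble::as_tibble(units)
  p <- ggplot2::ggplot(units)
  if (!is.null(centromeres) && nrow(centromeres) > 0) {
    p <- p + ggplot2::geom_rect(
      data = centromeres,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -0.4, ymax = 0.4),
      fill = "grey80"
    )
  }
  p +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = 0, yend = 0,
                   colour = if ("arm" %in% names(units)) .data$arm else NULL),
      linewidth = 4
    ) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$seq_id)) +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = "arm") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Block-size distribution
#'
#' @param blocks Block tibble from [call_blocks()].
#' @return A ggplot histogram of block sizes.
#' @export
plot_block_sizes <- function(blocks) {
  ggplot2::ggplot(blocks, ggplot2::aes(x = .data$n_units)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "units per block", y = "blocks") +
    ggplot2::theme_minimal()
}

#' Clade-by-location composition heatmap
#'
#' The tabular analogue of colouring a phylogeny by chromosome arm: rows
#' are major clades, columns chromosome-arm locations, cells unit counts.
#'
#' @param tab Long tibble from [cross_tab()].
#' @return A ggplot.
#' @export
plot_clade_locations <- function(tab) {
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$location, y = .data$clade,
                                    fill = .data$n)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "chromosome arm", y = "major clade", fill = "units") +
    ggplot2::theme_minimal()
}
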