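#' Plot a knockoff scan along the region
#'
#' W statistic against window midpoint, one panel per window size, selected
#' windows highlighted.
#'
#' @param object A `triokf_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot triokf_scan
#' @export
autoplot.triokf_scan <- function(object, ...) {
  df <- tibble::as_tibble(object[setdiff(names(object), "Zstar")])
  df$mid <- (df$start + df$end) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid / 1e6, y = .data$W)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 1) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~size, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red"),
                                 na.value = "grey80") +
    ggplot2::labs(x = "position (Mb)", y = "W = |Z| / median |Z*|",
                  colour = "selected")
}

#' Plot an analytic power grid
#'
#' Power against minor allele frequency, one line per odds ratio.
#'
#' @param object A `triokf_power`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot triokf_power
#' @export
autoplot.triokf_power <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$maf, y = .data$power,
                                   colour = factor(.data$or),
                                   group = factor(.data$or))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "minor allele frequency", y = "power",
                  colour = "odds ratio")
}

#' Plot LD blocks over the banded r-squared matrix
#'
#' @param r2 Long-format tibble from [ld_r2_matrix()].
#' @param positions Variant positions.
#' @param blocks Optional `triokf_blocks` to overlay.
#' @return A ggplot object.
#' @export
plot_ld <- function(r2, positions, blocks = NULL) {
  df <- r2
  df$x <- positions[df$i] / 1e6
  df$y <- positions[df$j] / 1e6
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$r2)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = "position (Mb)", y = "position (Mb)", colour = "r2")
  if (!is.null(blocks)) {
    p <- p + ggplot2::geom_vline(xintercept = blocks$start_bp / 1e6,
                                 linewidth = 0.2, colour = "grey50")
  }
  p
}
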