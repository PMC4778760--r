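#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Composite-score landscape of a selection scan
#'
#' Manhattan-style plot of the composite score along each contig, with
#' called regions shaded and the top-k score threshold drawn.
#'
#' @param object A `selection_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot selection_scan
#' @export
autoplot.selection_scan <- function(object, ...) {
  w <- object$windows
  p <- ggplot2::ggplot(w, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                       y = .data$cms)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = object$cms_threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~contig, ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = "composite score (1 - q product)") +
    ggplot2::theme_minimal()
  if (nrow(object$regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, fill = "firebrick", alpha = 0.15,
      inherit.aes = FALSE
    )
  }
  p
}

#' Observed statistics against the simulated neutral null
#'
#' Overlays the density of each observed window statistic on its simulated
#' null distribution, the visual check that motivates simulation-calibrated
#' p-values (an excess right tail signals candidate sweeps).
#'
#' @param object A `null_dist`.
#' @param observed Optional window tibble with `delta_pi`, `fst`,
#'   `delta_td` columns.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot null_dist
#' @export
autoplot.null_dist <- function(object, observed = NULL, ...) {
  nd <- tidy(object)
  nd$source <- "simulated null"
  if (!is.null(observed)) {
    obs <- tidyr::pivot_longer(
      observed[c("delta_pi", "fst", "delta_td")],
      cols = dplyr::everything(),
      names_to = "statistic", values_to = "value"
    )
    obs <- obs[!is.na(obs$value), ]
    obs$source <- "observed"
    nd <- dplyr::bind_rows(nd, obs)
  }
  ggplot2::ggplot(nd, ggplot2::aes(x = .data$value, colour = .data$source)) +
    ggplot2::geom_density(na.rm = TRUE) +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = NULL, y = "density") +
    ggplot2::theme_minimal()
}

#' Biplot of two statistics coloured by window classification
#'
#' @param scan Classified window tibble (see [classify_windows()]).
#' @param x,y Statistic columns to plot (defaults `delta_pi`, `fst`).
#' @return A ggplot.
#' @export
plot_classification <- function(scan, x = "delta_pi", y = "fst") {
  ggplot2::ggplot(
    scan[!is.na(scan$class_label), ],
    ggplot2::aes(x = .data[[x]], y = .data[[y]], colour = .data$class_label)
  ) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(
      "low-CMS/high-FDR" = "grey60", "high-CMS/high-FDR" = "steelblue",
      "low-CMS/low-FDR" = "orange", "high-CMS/low-FDR" = "firebrick"
    ), drop = FALSE) +
    ggplot2::labs(colour = "window class") +
    ggplot2::theme_minimal()
}
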