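# Figure-style reporting: heatmap of the Welch sweep (cells show uncorrected
# p values, color encodes Cohen's d) — a pure function of the sweep table.

#' Sweep heatmap
#'
#' Renders the density-sweep group comparison as a tile grid: one panel per
#' metric, densities on the x axis, band x condition on the y axis, fill by
#' Cohen's d (positive = higher in the first group), p values printed in the
#' cells and run-surviving cells outlined.
#'
#' @param sweep a `sweep_result` from [sweep_group_tests()], or its `cells`
#'   data frame
#' @return a ggplot object
#' @export
sweep_heatmap <- function(sweep) {
  cells <- if (inherits(sweep, "sweep_result")) sweep$cells else sweep
  stopifnot(all(c("metric", "band", "condition", "density", "p", "d_effect")
                %in% names(cells)))
  cells$row <- paste(cells$band, cells$condition)
  cells$dens <- factor(format(cells$density, digits = 3),
                       levels = unique(format(sort(unique(cells$density)),
                                              digits = 3)))
  if (is.null(cells$in_run)) cells$in_run <- FALSE
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$dens, y = .data$row,
                                      fill = .data$d_effect)) +
    ggplot2::geom_tile(color = "grey60") +
    ggplot2::geom_tile(data = cells[cells$in_run, , drop = FALSE],
                       fill = NA, color = "black", linewidth = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$p)),
                       size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", midpoint = 0,
                                  name = "Cohen's d") +
    ggplot2::facet_wrap(~metric, ncol = 1) +
    ggplot2::labs(x = "network density", y = "band / condition") +
    ggplot2::theme_minimal()
}
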