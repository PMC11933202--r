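#' Plot baseline-relative group series
#'
#' Figure-ready line plot of the relative change per wealth group and country
#' (7-day rolling mean when present), in the layout used throughout the
#' analysis: one panel per country, one coloured line per group.
#'
#' @param series A `mobgap_group_series`.
#' @param smooth Use the `rel_roll` column when available.
#' @return A ggplot object.
#' @export
plot_group_series <- function(series, smooth = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  s <- as.data.table(series)
  ycol <- if (smooth && "rel_roll" %in% names(s)) "rel_roll" else "rel_change"
  ggplot2::ggplot(s, ggplot2::aes(x = date, y = .data[[ycol]],
                                  colour = group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~country) +
    ggplot2::labs(x = NULL, y = "relative change vs baseline (%)",
                  colour = "wealth group") +
    ggplot2::theme_minimal()
}
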