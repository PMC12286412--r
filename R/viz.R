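## Explainability heatmaps of the cumulative and temporal variation blocks.

.heatmapFrame <- function(block, event, taus, variables) {
  ie <- match(as.integer(event), eventIndices(block))
  if (is.na(ie)) stop("unknown event index: ", event)
  it <- match(as.integer(taus), windowSizes(block))
  if (anyNA(it)) stop("tau set not contained in the block's window set")
  iv <- match(variables, fwfVariables(block))
  if (anyNA(iv)) stop("unknown variable(s): ",
                      paste(variables[is.na(iv)], collapse = ", "))
  vals <- fwfValues(block)[iv, ie, it, drop = FALSE]
  data.frame(
    variable = factor(rep(variables, times = length(taus)),
                      levels = variables),
    tau = factor(rep(taus, each = length(variables)), levels = rev(taus)),
    value = as.vector(vals)
  )
}

#' Render the cumulative and temporal variation heatmaps for one event
#'
#' Draws the per-player explainability view: two heatmap panels with
#' variables on the x axis and window sizes tau on the y axis, one for the
#' cumulative block (sequential palette, non-negative sums) and one for the
#' temporal block (diverging palette centered at zero, signed differences).
#' Colors are monotone in cell value. Written to `outPath` as PNG.
#'
#' @param cumulative a [TFWFMatrix-class] of kind `"cumulative"`.
#' @param temporal a [TFWFMatrix-class] of kind `"temporal"` sharing the
#'   variable, event and tau axes.
#' @param event 0-based event index to display.
#' @param outPath output file path (PNG).
#' @param taus window sizes to display (default: all in the blocks).
#' @param variables variable subset (default: all).
#' @param annotation optional subtitle string (player, date, context).
#' @param width,height,dpi device settings passed to [ggplot2::ggsave()].
#' @return `outPath`, invisibly. The input matrices are never modified.
#' @export
renderFWFHeatmaps <- function(cumulative, temporal, event, outPath,
                              taus = windowSizes(cumulative),
                              variables = fwfVariables(cumulative),
                              annotation = NULL,
                              width = 8, height = 4.5, dpi = 96) {
  stopifnot(is(cumulative, "TFWFMatrix"), is(temporal, "TFWFMatrix"))
  if (cumulative@kind != "cumulative" || temporal@kind != "temporal")
    stop("pass the cumulative block first and the temporal block second")
  if (!identical(fwfVariables(cumulative), fwfVariables(temporal)) ||
      !identical(windowSizes(cumulative), windowSizes(temporal)))
    stop("the two blocks must share variable and tau axes")
  if (length(taus) == 0L) stop("tau set must be non-empty")

  dCum <- .heatmapFrame(cumulative, event, taus, variables)
  dTmp <- .heatmapFrame(temporal, event, taus, variables)
  lim <- max(abs(dTmp$value), .Machine$double.eps)

  base <- function(d) {
    ggplot2::ggplot(d, ggplot2::aes(x = variable, y = tau, fill = value)) +
      ggplot2::geom_tile(color = "grey85", linewidth = 0.2) +
      ggplot2::labs(x = "variable", y = "window size (events)") +
      ggplot2::theme_minimal(base_size = 9) +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  }
  pCum <- base(dCum) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = "AW") +
    ggplot2::ggtitle("Cumulative variations")
  pTmp <- base(dTmp) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  limits = c(-lim, lim), name = "ΔACW") +
    ggplot2::ggtitle("Temporal variations")
  combined <- patchwork::wrap_plots(pCum, pTmp, ncol = 2L) +
    patchwork::plot_annotation(
      title = paste0("Workload footprint of ", fwfPlayer(cumulative),
                     " at event ", event),
      subtitle = annotation)
  ggplot2::ggsave(outPath, combined, width = width, height = height,
                  dpi = dpi, device = grDevices::png, bg = "white")
  invisible(outPath)
}
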