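#' Plot the percentage of PLA-positive cells per population
#'
#' Bar chart of `pct_pla_pos` by population, faceted by sample — the
#' per-sample readout of the gating pipeline.
#'
#' @param object A `plic_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot plic_result
#' @export
autoplot.plic_result <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$population,
                                  y = .data$pct_pla_pos)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d/%d", .data$n_pos,
                                                    .data$n)),
                       vjust = -0.4, size = 3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample)) +
    ggplot2::labs(x = NULL, y = "% PLA-positive cells") +
    ggplot2::theme_bw()
}

#' Plot a group comparison
#'
#' One point per independent experiment, with the group mean and s.e.m.
#' overlaid, as PLA quantification figures are conventionally drawn.
#'
#' @param object A `plic_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot plic_comparison
#' @export
autoplot.plic_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$group, y = .data$mean_pct)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, shape = 17, size = 2.5) +
    ggplot2::geom_errorbar(
      data = object$groups,
      ggplot2::aes(y = .data$mean_pct, ymin = .data$mean_pct,
                   ymax = .data$mean_pct + .data$sem), width = 0.25) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "% PLA-positive cells",
                  subtitle = sprintf("%s t-test: p = %.3g", object$method,
                                     object$p_value)) +
    ggplot2::theme_bw()
}

#' Display the channels of one cell
#'
#' Raster panels of each channel's pixel grid, on a shared or per-channel
#' intensity scale.
#'
#' @param cell A [cell_image()].
#' @param scale `"channel"` (default): each panel uses its own scale;
#'   `"shared"`: one scale across channels.
#' @return A ggplot.
#' @export
plot_cell <- function(cell, scale = c("channel", "shared")) {
  stopifnot(inherits(cell, "cell_image"))
  scale <- match.arg(scale)
  df <- purrr::imap(cell$channels, function(g, nm) {
    tibble::tibble(channel = nm,
                   row = as.vector(row(g)), col = as.vector(col(g)),
                   intensity = as.vector(g),
                   value = if (scale == "channel" && max(g) > 0) {
                     as.vector(g) / max(g)
                   } else {
                     as.vector(g)
                   })
  }) |> dplyr::bind_rows()
  df$channel <- factor(df$channel, levels = channel_names(cell))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), nrow = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(strip.text = ggplot2::element_text(size = 9))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
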