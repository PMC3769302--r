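# Rendering of the risk matrix. Cosmetic: the analysis lives in
# assess_risk(); this draws its output.

#' Plot the risk matrix
#'
#' Draws the response grid as shaded cells (likelihood = across-zone CV on
#' the x axis, consequence = stock total on the y axis, both linear),
#' each pool's points per epoch, and arrows for the epoch trajectories.
#'
#' @param assessment Result of [assess_risk()] (or the `assessment` element
#'   of [run_assessment()]).
#' @param grid The [response_grid()] used for the assessment.
#' @return A ggplot object.
#' @export
plot_risk_matrix <- function(assessment, grid = default_response_grid()) {
  cv_max <- max(c(assessment$cv_pct, grid$cv_breaks)) * 1.15
  stock_max <- max(c(assessment$stock_tg, grid$stock_breaks)) * 1.15
  cv_edges <- c(0, grid$cv_breaks, cv_max)
  stock_edges <- c(0, grid$stock_breaks, stock_max)
  cells <- expand.grid(row = seq_len(nrow(grid$categories)),
                       col = seq_len(ncol(grid$categories)))
  cells$category <- factor(grid$categories[as.matrix(cells)],
                           levels = risk_categories(), ordered = TRUE)
  cells$xmin <- cv_edges[cells$col]
  cells$xmax <- cv_edges[cells$col + 1]
  cells$ymin <- stock_edges[cells$row]
  cells$ymax <- stock_edges[cells$row + 1]

  epochs <- unique(assessment$epoch)
  traj <- tidyr::pivot_wider(
    assessment[, c("pool", "epoch", "stock_tg", "cv_pct")],
    names_from = "epoch", values_from = c("stock_tg", "cv_pct")
  )

  pal <- c(periodically_monitor = "#c7e9c0",
           annually_monitor_develop_strategies = "#fee391",
           initiate_adaptation_mitigation = "#fdae6b",
           robust_mitigation = "#de2d26")

  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = cells,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax,
                   fill = .data$category),
      alpha = 0.55, colour = "grey60"
    ) +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE,
                               name = "Response") +
    ggplot2::geom_point(
      data = assessment,
      ggplot2::aes(x = .data$cv_pct, y = .data$stock_tg,
                   shape = .data$epoch),
      size = 2.6
    ) +
    ggplot2::geom_text(
      data = assessment[assessment$epoch == epochs[1], ],
      ggplot2::aes(x = .data$cv_pct, y = .data$stock_tg,
                   label = pool_labels()[.data$pool]),
      vjust = -1, size = 3
    ) +
    ggplot2::labs(
      x = "Likelihood: across-zone CV of median C density (%)",
      y = "Consequence: total C stock (Tg)"
    ) +
    ggplot2::coord_cartesian(xlim = c(0, cv_max), ylim = c(0, stock_max),
                             expand = FALSE) +
    ggplot2::theme_minimal()
  if (length(epochs) == 2) {
    p <- p + ggplot2::geom_segment(
      data = traj,
      ggplot2::aes(x = .data[[paste0("cv_pct_", epochs[1])]],
                   y = .data[[paste0("stock_tg_", epochs[1])]],
                   xend = .data[[paste0("cv_pct_", epochs[2])]],
                   yend = .data[[paste0("stock_tg_", epochs[2])]]),
      arrow = ggplot2::arrow(length = ggplot2::unit(2.2, "mm")),
      linewidth = 0.4
    )
  }
  p
}
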