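#' Diagnostic plots
#'
#' Optional ggplot2-based figures: a PC biplot with the admixture-F3 circle
#' overlay, a bar chart of per-PC contributions to an F-statistic, and the
#' reference-axis residual rotation scatter. ggplot2 is in Suggests; these
#' functions error informatively when it is unavailable.
#'
#' @param d a `pc_decomp`.
#' @param circle optional `circle_region` from [admixture_circle()] (plotted
#'   in its first two subspace dimensions).
#' @param pcs which two PCs to plot.
#' @return a ggplot object.
#' @export
plot_biplot <- function(d, circle = NULL, pcs = c(1L, 2L)) {
  need_ggplot2()
  df <- data.frame(population = d$pop_labels,
                   x = d$coords[, pcs[1L]], y = d$coords[, pcs[2L]])
  pct <- 100 * d$eigenvalues / max(sum(d$eigenvalues), 1e-300)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$population),
                       vjust = -0.6, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = sprintf("PC%d (%.1f%%)", pcs[1L], pct[pcs[1L]]),
                  y = sprintf("PC%d (%.1f%%)", pcs[2L], pct[pcs[2L]]))
  if (!is.null(circle)) {
    th <- seq(0, 2 * pi, length.out = 181L)
    ring <- function(r, grp) data.frame(
      x = circle$center[1L] + r * cos(th),
      y = circle$center[2L] + r * sin(th), grp = grp)
    circ_df <- rbind(ring(circle$radius_full_ball, "projected n-ball"),
                     ring(circle$radius, "subspace circle"))
    p <- p + ggplot2::geom_path(
      data = circ_df,
      ggplot2::aes(x = .data$x, y = .data$y, linetype = .data$grp),
      colour = "grey40", inherit.aes = FALSE) +
      ggplot2::labs(linetype = NULL)
  }
  p
}

#' @rdname plot_biplot
#' @param s an `fstat_spectrum`.
#' @param max_pc show at most this many leading PCs.
#' @export
plot_spectrum <- function(s, max_pc = 10L) {
  need_ggplot2()
  k <- seq_len(min(max_pc, length(s$contributions)))
  df <- data.frame(pc = factor(k), contribution = s$contributions[k])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc, y = .data$contribution)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "PC",
                  y = sprintf("contribution to %s(%s)", s$kind,
                              paste(s$pops, collapse = ", ")))
}

#' @rdname plot_biplot
#' @param rr a `residual_rotation`.
#' @export
plot_residual_rotation <- function(rr) {
  need_ggplot2()
  df <- data.frame(population = names(rr$axis_pos), x = rr$axis_pos,
                   y = rr$residual_pcs[, 1L])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$population),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = sprintf("position along %s - %s axis",
                              rr$references[1L], rr$references[2L]),
                  y = "residual PC1")
}

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    fp_stop_capability("plotting requires the ggplot2 package")
  }
}
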