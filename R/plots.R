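#' M-D signal plot of a differential-expression result
#'
#' Scatter of per-feature log2 fold change (M) against absolute expression
#' difference (D, log10 axis), colored by call status, with the pooled
#' within-condition noise cloud in grey.
#'
#' @param object An `ffl_de`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ffl_de <- function(object, ...) {
  tab <- object$table
  noise <- object$noise
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$M, y = .data$D)) +
    ggplot2::geom_point(
      data = tibble(M = c(-noise$abs_m, noise$abs_m), D = rep(noise$d, 2)),
      color = "grey80", size = 0.3, alpha = 0.4
    ) +
    ggplot2::geom_point(ggplot2::aes(color = .data$status), size = 1.2) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_color_manual(values = c(
      up = "#d73027", down = "#4575b4", `not-DE` = "grey40"
    )) +
    ggplot2::labs(x = "M (log2 tumor/adjacent)", y = "D (|mean difference|)",
                  color = NULL, title = "Signal vs within-condition noise")
}

#' Plot a regulatory network
#'
#' Force-directed layout; node color by class, shape by DE direction, edge
#' color by regulator type (TF-target vs miRNA-target).
#'
#' @param object A `regnet`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.regnet <- function(object, seed = 1L, ...) {
  g <- regnet_igraph(object, directed = TRUE)
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- mutate(object$nodes[match(igraph::V(g)$name, object$nodes$node), ],
                  x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    mutate(
      x = nodes$x[match(.data$regulator, nodes$node)],
      y = nodes$y[match(.data$regulator, nodes$node)],
      xend = nodes$x[match(.data$target, nodes$node)],
      yend = nodes$y[match(.data$target, nodes$node)]
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
                   color = .data$edge_type),
      linewidth = 0.3, alpha = 0.6
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$class,
                   shape = .data$direction),
      size = 3
    ) +
    ggplot2::scale_shape_manual(values = c(up = 24, down = 25)) +
    ggplot2::scale_color_manual(values = c(`tf-target` = "#7b3294",
                                           `mirna-target` = "#d7191c")) +
    ggplot2::scale_fill_manual(values = c(TF = "#fdae61", miRNA = "#abd9e9",
                                          gene = "#a6d96a")) +
    ggplot2::guides(fill = ggplot2::guide_legend(override.aes = list(shape = 21))) +
    ggplot2::theme_void() +
    ggplot2::labs(color = "edge", fill = "class", shape = "DE direction")
}

#' Kaplan-Meier plot of a survival stratification
#'
#' @param object An `ffl_survival` from [survival_report()].
#' @param ... Unused.
#' @return A ggplot of the two arms' step curves with the log-rank p in the
#'   subtitle.
#' @export
autoplot.ffl_survival <- function(object, ...) {
  curves <- object$curves |>
    group_by(.data$arm) |>
    group_modify(~ bind_rows(tibble(time = 0, surv = 1), .x[c("time", "surv")])) |>
    ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$surv,
                                       color = .data$arm)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Months", y = "Overall survival",
      title = sprintf("Survival by %s grouping", object$rule$mode),
      subtitle = sprintf("log-rank p = %.3g", object$logrank$p),
      color = NULL
    )
}
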