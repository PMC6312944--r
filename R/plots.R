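#' Plot ward occupancy over time
#'
#' One line per ward with a dashed capacity line, the standard view for
#' spotting saturated wards and flow bottlenecks.
#'
#' @param result A `hospital_sim`.
#' @param wards Optional character vector restricting the wards shown.
#' @return A ggplot object.
#' @export
plot_occupancy <- function(result, wards = NULL) {
  occ <- occupancy_series(result)
  if (!is.null(wards)) occ <- occ[occ$ward %in% wards, ]
  ggplot2::ggplot(occ, ggplot2::aes(x = .data$step, y = .data$occupancy)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$capacity),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~ward, scales = "free_y") +
    ggplot2::labs(x = "step (hours)", y = "occupied beds",
                  title = "Ward occupancy") +
    ggplot2::theme_minimal()
}

#' Plot the waiting-time distribution
#'
#' Histogram of per-patient waits (arrival to first exit from the entry
#' ward) with the waiting-time target marked.
#'
#' @param result A `hospital_sim`.
#' @param target Target in steps; defaults to the configured value.
#' @return A ggplot object.
#' @export
plot_waiting_times <- function(result,
                               target = result$config$settings$waiting_time_target) {
  wt <- waiting_times(result, target)
  ggplot2::ggplot(wt$waits, ggplot2::aes(x = .data$wait)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = -0.5,
                            fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = target + 0.5, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "waiting time (steps)", y = "patients",
                  title = sprintf("A&E waits: %.1f%% within %d steps",
                                  wt$pct_within_target, as.integer(target))) +
    ggplot2::theme_minimal()
}

#' Plot the realised patient-flow network
#'
#' Nodes are wards (plus the external world and discharge), sized by total
#' weighted degree; edge width encodes transfer counts.
#'
#' @param net A `flow_network` from [build_flow_network()].
#' @param seed Layout seed for reproducible node placement.
#' @return A ggplot object.
#' @export
plot_flow_network <- function(net, seed = 1) {
  stats <- network_statistics(net)
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = TRUE,
                                     vertices = data.frame(name = net$nodes))
  xy <- with_sim_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble::tibble(
    node = net$nodes, x = xy[, 1], y = xy[, 2],
    degree = stats$in_degree_weighted[match(net$nodes, stats$node)] +
      stats$out_degree_weighted[match(net$nodes, stats$node)]
  )
  seg <- dplyr::mutate(
    net$edges,
    x = nodes$x[match(.data$from, nodes$node)],
    y = nodes$y[match(.data$from, nodes$node)],
    xend = nodes$x[match(.data$to, nodes$node)],
    yend = nodes$y[match(.data$to, nodes$node)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$count),
      colour = "grey60",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree),
      colour = "steelblue"
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
      vjust = -1.2, size = 3
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::scale_size(range = c(2, 10)) +
    ggplot2::labs(title = "Patient-flow network",
                  size = "total degree", linewidth = "transfers") +
    ggplot2::theme_void()
}

#' @export
autoplot.hospital_sim <- function(object, ...) {
  plot_occupancy(object)
}

#' @export
autoplot.flow_network <- function(object, ...) {
  plot_flow_network(object)
}

#' @export
autoplot.flow_analysis <- function(object, ...) {
  occ <- object$occupancy
  ggplot2::ggplot(occ, ggplot2::aes(x = .data$step, y = .data$occupancy)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$capacity),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~ward, scales = "free_y") +
    ggplot2::labs(x = "step (hours)", y = "occupied beds") +
    ggplot2::theme_minimal()
}
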