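#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_text
#'   geom_path geom_tile coord_fixed theme_void theme_minimal labs
#'   scale_fill_gradient
NULL

head_outline <- function() {
  th <- seq(0, 2 * pi, length.out = 181)
  tibble::tibble(x = 1.1 * cos(th), y = 1.1 * sin(th))
}

head_plot_base <- function(montage) {
  nose <- tibble::tibble(x = c(-0.12, 0, 0.12), y = c(1.09, 1.22, 1.09))
  ggplot(montage, aes(x = .data$x, y = .data$y)) +
    geom_path(data = head_outline(), linewidth = 0.3, colour = "grey40") +
    geom_path(data = nose, linewidth = 0.3, colour = "grey40") +
    geom_point(size = 1.2, colour = "grey30") +
    geom_text(aes(label = .data$label), size = 2.2, vjust = -1,
              colour = "grey30") +
    coord_fixed() + theme_void()
}

edge_coords <- function(edges, montage) {
  pos <- montage[, c("label", "x", "y")]
  edges |>
    dplyr::left_join(pos, by = c(chan_i = "label")) |>
    dplyr::rename(x_i = "x", y_i = "y") |>
    dplyr::left_join(pos, by = c(chan_j = "label")) |>
    dplyr::rename(x_j = "x", y_j = "y")
}

#' Head plot of a thresholded group graph
#'
#' Channels on the schematic head plane, connected where the group
#' median coherence reaches the threshold (the standard connectivity
#' head-map display).
#'
#' @param object A [threshold_graph()] result.
#' @param montage The [montage()] used (required for positions).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot group_graph
#' @export
autoplot.group_graph <- function(object, montage, ...) {
  p <- head_plot_base(montage)
  if (nrow(object$edges)) {
    p <- p + geom_segment(
      data = edge_coords(object$edges, montage),
      aes(x = .data$x_i, y = .data$y_i, xend = .data$x_j, yend = .data$y_j),
      colour = "black", linewidth = 0.3, alpha = 0.7)
  }
  p + labs(title = sprintf("%s / %s / %s: median coherence >= %g",
                           object$group, object$condition, object$band,
                           object$threshold))
}

#' Head plot of a significant-difference graph
#'
#' Case-deficit edges (FDR-significant pairs where the case median is
#' weaker) drawn in blue on the schematic head plane.
#'
#' @param object A [difference_graph()].
#' @param montage The [montage()] used.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot difference_graph
#' @export
autoplot.difference_graph <- function(object, montage, ...) {
  p <- head_plot_base(montage)
  if (nrow(object$edges)) {
    p <- p + geom_segment(
      data = edge_coords(object$edges, montage),
      aes(x = .data$x_i, y = .data$y_i, xend = .data$x_j, yend = .data$y_j),
      colour = "blue", linewidth = 0.4, alpha = 0.8)
  }
  p + labs(title = sprintf("%s / %s: case-deficit edges at q <= %g",
                           object$band, object$condition, object$q_cutoff))
}

#' Coherence matrix heatmap
#'
#' @param m Symmetric channels x channels coherence matrix.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_coherence_matrix <- function(m, title = "Band coherence") {
  labels <- rownames(m)
  d <- tidyr::expand_grid(chan_i = labels, chan_j = labels) |>
    dplyr::mutate(coherence = as.vector(t(m)))
  ggplot(d, aes(x = factor(.data$chan_j, labels),
                y = factor(.data$chan_i, rev(labels)),
                fill = .data$coherence)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick", limits = c(0, 1)) +
    coord_fixed() + theme_minimal(base_size = 8) +
    labs(x = NULL, y = NULL, title = title)
}
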