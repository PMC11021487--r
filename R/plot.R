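#' Plot a vascular network map
#'
#' Draws segments as lines between node coordinates, with line width
#' proportional to diameter. Requires node positions (`x_um`, `y_um`).
#'
#' @param object A `vasc_network`.
#' @param colour_by Optional per-segment values (named by segment id) to
#'   colour the map, e.g. normalized flows or uncertainty indices.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vasc_network
#' @export
autoplot.vasc_network <- function(object, colour_by = NULL, ...) {
  if (all(is.na(object$nodes$x_um))) {
    abort("network has no node coordinates to plot")
  }
  segs <- tidy(object) |>
    left_join(object$nodes |> select("node_id", xa = "x_um", ya = "y_um"),
              by = c(node_a = "node_id")) |>
    left_join(object$nodes |> select("node_id", xb = "x_um", yb = "y_um"),
              by = c(node_b = "node_id"))
  p <- if (is.null(colour_by)) {
    ggplot2::ggplot(segs) +
      ggplot2::geom_segment(
        ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                     yend = .data$yb, linewidth = .data$diameter_um,
                     colour = .data$vessel_class)
      )
  } else {
    segs$value <- unname(colour_by[segs$segment_id])
    ggplot2::ggplot(segs) +
      ggplot2::geom_segment(
        ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                     yend = .data$yb, linewidth = .data$diameter_um,
                     colour = .data$value)
      ) +
      ggplot2::scale_colour_viridis_c(option = "plasma")
  }
  p +
    ggplot2::scale_linewidth(range = c(0.3, 3), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot per-segment flow histograms over annealing restarts
#'
#' The restart-ensemble histogram of a segment's normalized flow shows how
#' strongly the observations pin it down: tightly pinned vessels give a
#' single narrow mode, collateral-capable vessels a broad or multi-modal
#' distribution with mass at or near zero.
#'
#' @param object A `vasc_ensemble`.
#' @param segments Segment ids to show (default: the four highest
#'   uncertainty indices).
#' @param bins Histogram bins (default 30).
#' @param ... Unused.
#' @return A ggplot object, faceted by segment.
#' @method autoplot vasc_ensemble
#' @export
autoplot.vasc_ensemble <- function(object, segments = NULL, bins = 30, ...) {
  if (is.null(segments)) {
    segments <- head(rank_collateral_candidates(object)$segment_id, 4)
  }
  df <- as_tibble(as.data.frame(object$samples[, segments, drop = FALSE])) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "segment_id",
                        values_to = "flow_normalized")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$flow_normalized)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::facet_wrap(~segment_id, scales = "free") +
    ggplot2::labs(x = "normalized flow (reference = 1000)",
                  y = "restarts") +
    ggplot2::theme_minimal()
}

#' Plot an annealing trace
#'
#' @param object A `vasc_anneal` run with `keep_trace = TRUE`.
#' @param ... Unused.
#' @return A ggplot of error and temperature against iteration.
#' @method autoplot vasc_anneal
#' @export
autoplot.vasc_anneal <- function(object, ...) {
  tr <- tidy(object) |>
    tidyr::pivot_longer(c("error", "temperature"),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Plot a pre/post ablation comparison
#'
#' @param object A `vasc_comparison`.
#' @param ... Unused.
#' @return A ggplot of post- against pre-ablation normalized flow,
#'   reversed segments highlighted.
#' @method autoplot vasc_comparison
#' @export
autoplot.vasc_comparison <- function(object, ...) {
  ggplot2::ggplot(object$comparison,
                  ggplot2::aes(x = .data$flow_pre, y = .data$flow_post,
                               colour = .data$reversed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "pre-ablation normalized flow",
                  y = "post-ablation normalized flow") +
    ggplot2::theme_minimal()
}

#' Plot a binned diameter distribution
#'
#' @param histogram Output of [diameter_histogram()].
#' @return A ggplot bar chart faceted by vessel class.
#' @export
plot_diameter_histogram <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = .data$bin_center, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~vessel_class, ncol = 1) +
    ggplot2::labs(x = "diameter bin center (µm)", y = "count") +
    ggplot2::theme_minimal()
}
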