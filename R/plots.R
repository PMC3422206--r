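# ggplot2 views of the main result types.

#' Replicate-versus-replicate enrichment scatter
#'
#' Scores of the first two background comparisons for every library k-mer,
#' colored by the enrichment call; the dashed lines mark the calling
#' threshold.
#'
#' @param records `enrichment_records` with an `enriched` column.
#' @param max_points cap on plotted k-mers (deterministic subsample).
#' @return A ggplot object.
#' @export
plot_enrichment_scatter <- function(records, max_points = 20000L) {
  df <- as_tibble(records)
  thr <- attr(records, "threshold_log2") %||% 1
  if (nrow(df) > max_points) {
    df <- df[round(seq(1, nrow(df), length.out = max_points)), ]
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$score_1, .data$score_2,
                                   colour = .data$enriched)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2) +
    ggplot2::geom_vline(xintercept = thr, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 ChIP/background (replicate 1)",
                  y = "log2 ChIP/background (replicate 2)",
                  colour = "enriched") +
    ggplot2::theme_minimal()
}

#' Windowed satellite density along assembly chromosomes
#'
#' @param densities tibble from [windowed_family_density()].
#' @return A ggplot object.
#' @export
plot_window_density <- function(densities) {
  ggplot2::ggplot(densities,
                  ggplot2::aes((.data$start + .data$end) / 2e3,
                               .data$masked_bp, fill = .data$gap_adjacent)) +
    ggplot2::geom_col(width = (densities$end[1] - densities$start[1]) / 1e3) +
    ggplot2::facet_grid(family ~ chrom, scales = "free") +
    ggplot2::labs(x = "position (kb)", y = "masked bp / window",
                  fill = "gap adjacent") +
    ggplot2::theme_minimal()
}

#' Mate-pair network plot
#'
#' Nodes on a circle, sized by read depth; edge width follows the mate-pair
#' count.
#'
#' @param network a `pair_network`.
#' @return A ggplot object.
#' @export
plot_pair_network <- function(network) {
  nd <- network$nodes
  nd$angle <- 2 * pi * (seq_len(nrow(nd)) - 1) / nrow(nd)
  nd$x <- cos(nd$angle); nd$y <- sin(nd$angle)
  ed <- network$edges |>
    left_join(nd[, c("label", "x", "y")], by = c(a = "label")) |>
    rename(x0 = "x", y0 = "y") |>
    left_join(nd[, c("label", "x", "y")], by = c(b = "label"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x, yend = .data$y,
                                       linewidth = .data$count),
                          colour = "grey60") +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(.data$x, .data$y, size = .data$weight),
                        colour = "steelblue") +
    ggplot2::geom_text(data = nd,
                       ggplot2::aes(.data$x * 1.15, .data$y * 1.15,
                                    label = .data$label), size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Enrichment coverage track over a contig
#'
#' @param track BEDGraph-style tibble from [map_enrichment_to_contigs()].
#' @param contig optional contig id to show (default: first).
#' @return A ggplot object.
#' @export
plot_contig_track <- function(track, contig = NULL) {
  contig <- contig %||% track$seq_id[1]
  df <- track[track$seq_id == contig, , drop = FALSE]
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = 0, ymax = .data$value),
                       fill = "firebrick") +
    ggplot2::labs(x = paste0(contig, " position (bp)"),
                  y = "enriched k-mer depth") +
    ggplot2::theme_minimal()
}

#' @describeIn select_k_and_cluster silhouette profile over k with the
#'   chosen k marked.
#' @param object a `window_clustering`.
#' @param ... ignored.
#' @method autoplot window_clustering
#' @export
autoplot.window_clustering <- function(object, ...) {
  ggplot2::ggplot(object$silhouettes,
                  ggplot2::aes(.data$k, .data$mean_silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "k", y = "mean silhouette") +
    ggplot2::theme_minimal()
}
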