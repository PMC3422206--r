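# broom-style accessors for fitted objects.

#' Tidy a window clustering
#'
#' @param x a `window_clustering`.
#' @param ... ignored.
#' @return Tibble `(row, cluster)` of assignments.
#' @method tidy window_clustering
#' @export
tidy.window_clustering <- function(x, ...) {
  x$assignments
}

#' @rdname tidy.window_clustering
#' @return `glance()`: a one-row tibble `(chosen_k, mean_silhouette,
#'   n_rows, largest_cluster)`.
#' @method glance window_clustering
#' @export
glance.window_clustering <- function(x, ...) {
  tibble(chosen_k = x$chosen_k, mean_silhouette = x$mean_silhouette,
         n_rows = nrow(x$assignments), largest_cluster = max(x$sizes))
}

#' Tidy a pair network
#'
#' @param x a `pair_network`.
#' @param ... ignored.
#' @return The edge tibble `(a, b, count)`.
#' @method tidy pair_network
#' @export
tidy.pair_network <- function(x, ...) x$edges

#' @rdname tidy.pair_network
#' @method glance pair_network
#' @export
glance.pair_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         edge_threshold = x$edge_threshold,
         total_pairs = sum(x$edges$count))
}

#' Tidy a copy-number calibration
#'
#' @param x a `copy_calibration`.
#' @param ... ignored.
#' @return One-row tibble `(mu_sc, sd_sc, coverage, source)`.
#' @method tidy copy_calibration
#' @export
tidy.copy_calibration <- function(x, ...) {
  tibble(mu_sc = x$mu_sc, sd_sc = x$sd_sc, coverage = x$coverage,
         source = x$source)
}
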