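# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' Tidy a fitted negative-binomial background model
#'
#' @param x An `nb_background`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @exportS3Method generics::tidy
tidy.nb_background <- function(x, ...) {
  tibble(term = c("mean", "dispersion", "scale"),
         estimate = c(x$mean, x$dispersion, x$scale))
}

#' One-row summary of a fitted background model
#'
#' @param x An `nb_background`.
#' @param ... Unused.
#' @return One-row tibble (`bin_size`, `mean`, `dispersion`, `scale`,
#'   `n_bins`).
#' @exportS3Method generics::glance
glance.nb_background <- function(x, ...) {
  tibble(bin_size = x$bin_size, mean = x$mean, dispersion = x$dispersion,
         scale = x$scale, n_bins = x$n_bins)
}

#' Per-site tidy view of a co-binding clustering
#'
#' @param x A `cobind_clusters`.
#' @param ... Unused.
#' @return Tibble with `site`, `cluster` and (when labeled) `label`.
#' @exportS3Method generics::tidy
tidy.cobind_clusters <- function(x, ...) {
  out <- tibble(site = seq_along(x$cluster), cluster = x$cluster)
  if (!is.null(x$site_label)) out$label <- x$site_label
  out
}

#' One-row summary of a co-binding clustering
#'
#' @param x A `cobind_clusters`.
#' @param ... Unused.
#' @return One-row tibble (`k`, `n`, `tot_withinss`, `n_init`, `seed`,
#'   `ambiguous`).
#' @exportS3Method generics::glance
glance.cobind_clusters <- function(x, ...) {
  tibble(k = x$k, n = length(x$cluster), tot_withinss = x$tot_withinss,
         n_init = x$n_init, seed = x$seed, ambiguous = x$ambiguous)
}

z_matrix_long <- function(z, clusters = NULL) {
  nw <- attr(z, "n_subwindows")
  if (is.null(nw)) nw <- ncol(z) %/% 2L
  m <- unclass(z)
  long <- tibble(
    site = rep(seq_len(nrow(m)), times = ncol(m)),
    column = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
  long$track <- ifelse(long$column <= nw, "factor A", "factor B")
  long$subwindow <- ifelse(long$column <= nw, long$column, long$column - nw)
  if (!is.null(clusters)) {
    lab <- if (!is.null(clusters$site_label)) clusters$site_label else
      as.character(clusters$cluster)
    long$label <- lab[long$site]
    # display order: cluster label, then total intensity within the site
    intensity <- rowSums(m)
    site_rank <- order(lab, -intensity)
    long$row <- match(long$site, site_rank)
  } else {
    long$row <- long$site
  }
  long
}

#' Heatmap of a z-scored co-binding profile matrix
#'
#' Rows are sites (sorted by cluster label then intensity when a clustering
#' is supplied), columns the 25-bp sub-windows of the two factor tracks.
#'
#' @param object A `z_matrix`.
#' @param clusters Optional `cobind_clusters` used to sort and facet rows.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.z_matrix <- function(object, clusters = NULL, ...) {
  long <- z_matrix_long(object, clusters)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$subwindow, y = .data$row,
                                          fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  name = "z") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "sub-window", y = "binding site") +
    ggplot2::theme_minimal()
  if (!is.null(clusters)) {
    p <- p + ggplot2::facet_grid(label ~ track, scales = "free_y",
                                 space = "free_y")
  } else {
    p <- p + ggplot2::facet_grid(. ~ track)
  }
  p
}

#' Heatmap of co-binding classification results
#'
#' @param object A `cobind_clusters`.
#' @param z The `z_matrix` the clustering was fitted on.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cobind_clusters <- function(object, z, ...) {
  autoplot.z_matrix(z, clusters = object)
}

#' Bar chart of proximal/distal/unassigned site fractions
#'
#' @param summary One-row tibble from [tss_distance_summary()].
#' @return A ggplot object.
#' @export
plot_tss_distance <- function(summary) {
  long <- tidyr::pivot_longer(
    summary[, c("proximal", "distal", "unassigned")],
    dplyr::everything(), names_to = "class", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "fraction of sites") +
    ggplot2::theme_minimal()
}

#' Bar chart of motif-containing site proportions per co-binding class
#'
#' @param motif_summary Tibble with `label` and `fraction` columns (as
#'   produced by the motif stage of [run_pipeline()]).
#' @return A ggplot object.
#' @export
plot_motif_proportions <- function(motif_summary) {
  ggplot2::ggplot(motif_summary,
                  ggplot2::aes(x = .data$label, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d/%d", .data$n_with_motif, .data$n_total)),
      vjust = -0.4, size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "co-binding class",
                  y = "fraction of sites with motif") +
    ggplot2::theme_minimal()
}
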