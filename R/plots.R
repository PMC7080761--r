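#' Plot a 2D density or differential-density map
#'
#' Differential maps use a diverging palette centered at zero (positive =
#' cKO-enriched, negative = control-enriched).
#'
#' @param object A `waterfall_density` / `waterfall_diff_density`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.waterfall_density <- function(object, ...) {
  df <- expand.grid(x = object$x, y = object$y)
  df$z <- as.vector(object$z)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::labs(x = "axis 1", y = "axis 2") +
    ggplot2::theme_minimal()
  if (inherits(object, "waterfall_diff_density")) {
    p + ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                      high = "#B2182B", midpoint = 0,
                                      name = "log2 cKO/ctrl")
  } else {
    p + ggplot2::scale_fill_viridis_c(name = "density")
  }
}

#' Plot a SOM minimal spanning tree with condition enrichment
#'
#' Nodes are placed on the SOM grid, MST edges drawn between them, and each
#' occupied node colored by its normalized cKO share (0.5 = balanced).
#'
#' @param object A `waterfall_som`.
#' @param enrichment Optional tibble from [node_condition_enrichment()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.waterfall_som <- function(object, enrichment = NULL, ...) {
  nodes <- tibble::tibble(
    node = seq_len(nrow(object$codebook)),
    gx = object$grid_coords[, "gx"],
    gy = object$grid_coords[, "gy"],
    n_cells = as.integer(table(factor(object$assignment,
                                      levels = seq_len(nrow(object$codebook)))))
  )
  edges <- object$mst_edges
  edges$x <- nodes$gx[edges$from]; edges$y <- nodes$gy[edges$from]
  edges$xend <- nodes$gx[edges$to]; edges$yend <- nodes$gy[edges$to]
  if (!is.null(enrichment)) {
    nodes <- dplyr::left_join(nodes, enrichment, by = "node")
  } else {
    nodes$cko_share <- NA_real_
  }
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          color = "grey60") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$gx, y = .data$gy,
                                     size = .data$n_cells,
                                     color = .data$cko_share)) +
    ggplot2::scale_color_gradient2(low = "#2166AC", mid = "grey85",
                                   high = "#B2182B", midpoint = 0.5,
                                   limits = c(0, 1), name = "cKO share") +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::theme_void()
}

#' Plot cluster assignments on an embedding
#'
#' @param run A `waterfall_run` (needs `tsne` or `pca`).
#' @param use `"tsne"` or `"pca"`.
#' @return A ggplot.
#' @export
plot_clusters <- function(run, use = c("tsne", "pca")) {
  use <- match.arg(use)
  if (use == "tsne" && !is.null(run$tsne)) {
    df <- run$tsne
    df$cluster <- factor(run$clusters$labels[df$cell_id])
    ggplot2::ggplot(df, ggplot2::aes(x = .data$tsne1, y = .data$tsne2,
                                     color = .data$cluster)) +
      ggplot2::geom_point(size = 0.5) +
      ggplot2::theme_minimal()
  } else {
    df <- tibble::tibble(pc1 = run$pca$scores[, 1], pc2 = run$pca$scores[, 2],
                         cluster = factor(run$clusters$labels))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                     color = .data$cluster)) +
      ggplot2::geom_point(size = 0.5) +
      ggplot2::theme_minimal()
  }
}

#' QC scatter of library size vs detected genes
#'
#' @param qc Output of [cell_qc_mask()].
#' @return A ggplot with the QC thresholds drawn.
#' @export
plot_qc <- function(qc) {
  cfg <- analysis_config()
  ggplot2::ggplot(qc, ggplot2::aes(x = log10(pmax(.data$libsize, 1)),
                                   y = log10(pmax(.data$n_features, 1)),
                                   color = .data$keep)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = cfg$min_log10_libsize,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = cfg$min_log10_features,
                        linetype = "dashed") +
    ggplot2::labs(x = "log10 library size", y = "log10 detected genes") +
    ggplot2::theme_minimal()
}
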