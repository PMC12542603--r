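#' Plot a 2-D projection coloured by cluster label
#'
#' @param projection Cells-by-2 coordinate matrix (from [project_umap()]).
#' @param labels Optional per-cell labels (cluster ids, cell types, ...).
#' @param point_size Point size (default 0.5).
#' @return A ggplot object.
#' @export
plot_projection <- function(projection, labels = NULL, point_size = 0.5) {
  df <- tibble(umap1 = projection[, 1L], umap2 = projection[, 2L])
  if (!is.null(labels)) {
    df$label <- factor(ifelse(labels %in% -1L, "noise", as.character(labels)))
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$umap1, .data$umap2,
                                          colour = .data$label))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$umap1, .data$umap2))
  }
  p + ggplot2::geom_point(size = point_size, alpha = 0.7) +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Composition bar graph per cell type and condition
#'
#' Bars give each subcluster's percentage of its condition's non-noise cells
#' of that type.
#'
#' @param object A `composition_table` from [composition()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot composition_table
#' @export
autoplot.composition_table <- function(object, ...) {
  df <- object[object$subcluster > 0L, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$subcluster_label, .data$pct,
                                   fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~cell_type, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "% of condition's cells (non-noise)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Per-type UMAP panels of a subclustering
#'
#' @param object A `subclustering` from [subcluster_by_type()].
#' @param ... Unused.
#' @return A ggplot object (facetted by cell type).
#' @method autoplot subclustering
#' @export
autoplot.subclustering <- function(object, ...) {
  df <- purrr::map_dfr(names(object$detail), function(ty) {
    d <- object$detail[[ty]]
    tibble(cell_type = ty, umap1 = d$projection[, 1L],
           umap2 = d$projection[, 2L],
           label = ifelse(d$labels > 0L,
                          paste0(type_abbrev(ty), d$labels), "noise"))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$umap1, .data$umap2,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::facet_wrap(~cell_type, scales = "free") +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Marker log2 fold-change heat map
#'
#' Tile plot of a [log2fc_matrix()], genes on rows ordered as given.
#'
#' @param m Genes-by-clusters log2FC matrix.
#' @param max_genes Cap on rows shown (default 50).
#' @return A ggplot object.
#' @export
plot_log2fc_heatmap <- function(m, max_genes = 50L) {
  m <- m[seq_len(min(nrow(m), max_genes)), , drop = FALSE]
  df <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(m), gene = rownames(m)),
    -dplyr::all_of("gene"), names_to = "cluster", values_to = "log2fc")
  df$gene <- factor(df$gene, levels = rev(rownames(m)))
  ggplot2::ggplot(df, ggplot2::aes(.data$cluster, .data$gene,
                                   fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2FC") +
    ggplot2::theme_minimal()
}

#' Autoencoder training-loss curve
#'
#' @param object An `autoencoder`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot autoencoder
#' @export
autoplot.autoencoder <- function(object, ...) {
  ggplot2::ggplot(object$training_log,
                  ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "reconstruction MSE") +
    ggplot2::theme_minimal()
}
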