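#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line labs
#'   facet_wrap theme_minimal scale_colour_viridis_d
#' @export
ggplot2::autoplot

#' @describeIn embed_cells Scatter plot of the embedding, optionally
#'   coloured by a label vector.
#' @param object A `gate_embedding`.
#' @param labels Optional per-cell labels for colouring.
#' @param ... Ignored.
#' @export
autoplot.gate_embedding <- function(object, labels = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- if (is.null(labels)) {
    ggplot(df, aes(x = .data$umap_1, y = .data$umap_2)) +
      geom_point(size = 0.4, alpha = 0.6)
  } else {
    df$label <- as.character(labels)
    ggplot(df, aes(x = .data$umap_1, y = .data$umap_2, colour = .data$label)) +
      geom_point(size = 0.4, alpha = 0.6) +
      scale_colour_viridis_d()
  }
  p + labs(x = "UMAP 1", y = "UMAP 2") + theme_minimal()
}

#' @describeIn cluster_embedding Embedding scatter coloured by extracted
#'   cluster (noise in grey).
#' @param object A `gate_clustering`.
#' @param embedding The embedding that was clustered.
#' @param ... Ignored.
#' @export
autoplot.gate_clustering <- function(object, embedding, ...) {
  coords <- embedding_coords(embedding)
  df <- tibble::tibble(
    x = coords[, 1], y = coords[, 2],
    cluster = ifelse(is.na(object$cluster), "noise",
                     paste0("cluster_", object$cluster))
  )
  ggplot(df, aes(x = .data$x, y = .data$y, colour = .data$cluster)) +
    geom_point(size = 0.4, alpha = 0.6) +
    scale_colour_viridis_d() +
    labs(x = "UMAP 1", y = "UMAP 2", colour = "cluster") +
    theme_minimal()
}

#' @describeIn train_classifier Training and validation loss curves.
#' @param object A `gate_classifier`.
#' @param ... Ignored.
#' @export
autoplot.gate_classifier <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "series", values_to = "loss")
  h <- h[!is.na(h$loss), ]
  ggplot(h, aes(x = .data$epoch, y = .data$loss, colour = .data$series)) +
    geom_line() +
    labs(x = "epoch", y = "loss", colour = NULL) +
    theme_minimal()
}

#' @describeIn deepgate Unknown-pool embedding coloured by final label,
#'   one panel per label source.
#' @param object A `deepgate_result`.
#' @param ... Ignored.
#' @export
autoplot.deepgate_result <- function(object, ...) {
  if (is.null(object$embedding)) {
    counts <- dplyr::count(object$assignment, .data$label, .data$source)
    return(ggplot(counts, aes(x = .data$label, y = .data$n, fill = .data$source)) +
             ggplot2::geom_col() +
             labs(x = NULL, y = "cells") + theme_minimal() +
             ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)))
  }
  ids <- object$embedding$cell_id
  m <- match(ids, object$assignment$cell_id)
  df <- tibble::tibble(
    x = object$embedding$umap_1, y = object$embedding$umap_2,
    label = object$assignment$label[m], source = object$assignment$source[m]
  )
  ggplot(df, aes(x = .data$x, y = .data$y, colour = .data$label)) +
    geom_point(size = 0.4, alpha = 0.7) +
    facet_wrap(~source) +
    scale_colour_viridis_d() +
    labs(x = "UMAP 1", y = "UMAP 2", colour = "label") +
    theme_minimal()
}

#' Plot a 3-D label-axis view as stacked label planes
#'
#' Renders the [make_3d_view()] coordinate table in 2-D, one facet per
#' label plane (Z level), which is the static equivalent of rotating the
#' 3-D projection.
#'
#' @param view Tibble from [make_3d_view()].
#' @return A ggplot object.
#' @export
plot_label_planes <- function(view) {
  view$plane <- sprintf("z = %d: %s", as.integer(view$z), view$label)
  ggplot(view, aes(x = .data$x, y = .data$y, colour = .data$label)) +
    geom_point(size = 0.4, alpha = 0.7) +
    facet_wrap(~plane) +
    scale_colour_viridis_d() +
    labs(x = "UMAP 1", y = "UMAP 2") +
    theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
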