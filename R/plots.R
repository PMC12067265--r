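#' Plot a Kaplan-Meier estimate
#'
#' Step curves of the product-limit survival estimate per group.
#'
#' @param object a `ct_km` tibble from [km_estimate()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ct_km <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               color = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_point(data = dplyr::filter(object, .data$n_censor > 0),
                        shape = 3, show.legend = FALSE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot pre vs post clonotype counts per patient
#'
#' @param trajectories tibble from [diversity_trajectories()].
#' @return a ggplot object: pre on x, post on y, the identity line
#'   separating increased from flat patients.
#' @export
plot_trajectories <- function(trajectories) {
  ggplot2::ggplot(trajectories,
                  ggplot2::aes(x = .data$pre_count, y = .data$post_count,
                               color = .data$increased)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "Pre-treatment unique clonotypes",
                  y = "Post-treatment unique clonotypes",
                  color = "Increased") +
    ggplot2::theme_minimal()
}

#' Heatmap of cluster-blinding attribution deltas
#'
#' Genes by clusters, tile fill showing the change in correlation strength
#' when the cluster is blinded (positive: the cluster carries the
#' correlation).
#'
#' @param attribution a `ct_attribution` from [cluster_blinding_delta()].
#' @param genes optional subset/order of genes to display.
#' @return a ggplot object.
#' @export
plot_attribution <- function(attribution, genes = NULL) {
  stopifnot(inherits(attribution, "ct_attribution"))
  d <- attribution$delta
  if (!is.null(genes)) {
    d <- dplyr::filter(d, .data$gene %in% genes) |>
      dplyr::mutate(gene = factor(.data$gene, levels = genes))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cluster, y = .data$gene,
                                  fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = "Δ |R| on blinding") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Volcano plot of trajectory-group differential expression
#'
#' @param de a `ct_de` tibble from [differential_expression()].
#' @return a ggplot object (log2 fold change vs -log10 q, selected genes
#'   highlighted).
#' @export
plot_volcano <- function(de) {
  stopifnot(inherits(de, "ct_de"))
  d <- dplyr::filter(de, !.data$excluded)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc,
                                  y = -log10(pmax(.data$q, 1e-300)),
                                  color = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (increase vs no increase)",
                  y = "-log10 q", color = "Selected") +
    ggplot2::theme_minimal()
}

#' Plot a spatial cell map
#'
#' @param object a `ct_spatial_sample` from [generate_spatial_sample()] (or
#'   any tibble with `x_um`, `y_um`, `cell_type` passed via `object$cells`).
#' @param ... unused.
#' @return a ggplot object with fixed aspect ratio in micrometers.
#' @export
autoplot.ct_spatial_sample <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$x_um, y = .data$y_um,
                               color = .data$cell_type)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$sample_id,
                  x = "x (µm)", y = "y (µm)", color = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
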