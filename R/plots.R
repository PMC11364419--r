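#' Heatmap of clustered steady states
#'
#' Tile plot of z-normalised node expression across steady states, ordered
#' by cluster -- the simulated analogue of a clustered expression heatmap
#' of phenotypic states.
#'
#' @param object A `state_assignment` from [cluster_states()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.state_assignment <- function(object, ...) {
  df <- tidy(object)
  df$state_id <- seq_len(nrow(df))
  df <- df[order(df$cluster, -df$pigmentation_score), ]
  df$row <- seq_len(nrow(df))
  long <- tidyr::pivot_longer(df[, c("row", "cluster", object$norm$nodes)],
                              dplyr::all_of(object$norm$nodes),
                              names_to = "node", values_to = "z")
  long$node <- factor(long$node, levels = object$norm$nodes)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$node, y = .data$row,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", name = "z") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$cluster), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = NULL, y = "steady state",
                  title = "Phenotypic states (z-normalised expression)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Pigmentation-score histogram with kernel density
#'
#' Histogram of per-state pigmentation scores overlaid with a kernel
#' density estimate and the high-pigment threshold, showing the bimodal
#' coexistence of low- and high-pigment states.
#'
#' @param scores Numeric score vector (or a `state_assignment`).
#' @param threshold High-pigment cutoff drawn as a vertical line.
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, threshold = 0.22, bins = 60) {
  if (inherits(scores, "state_assignment")) {
    threshold <- scores$threshold
    scores <- scores$pigmentation_score
  }
  df <- tibble::tibble(score = scores)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_density(colour = "#B2182B", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "pigmentation score (mean z of MITF/LEF1)",
                  y = "density",
                  title = "Bimodal pigmentation-score distribution") +
    ggplot2::theme_minimal()
}

#' State-score heatmap plot
#'
#' Tile plot of the clusters x states "z-score of mean" matrix; a
#' diagonal-dominant pattern means each cluster scores highest on its own
#' state's marker set.
#'
#' @param object A `state_score_matrix` from [state_score_heatmap()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.state_score_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$cluster,
                                   fill = .data$z)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", name = "z of mean") +
    ggplot2::labs(x = "state gene set", y = "cell cluster",
                  title = "Gene-set activity by cluster") +
    ggplot2::theme_minimal()
}

#' Perturbation-comparison plot
#'
#' Per-replicate high-pigment fractions for control and perturbed
#' ensembles with the paired change drawn per seed.
#'
#' @param object A `perturbation_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perturbation_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(object$replicates,
                            c("control_fraction", "perturbed_fraction"),
                            names_to = "arm", values_to = "fraction")
  df$arm <- ifelse(df$arm == "control_fraction", "control",
                   sprintf("%s x%g", object$node, object$fold))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arm, y = .data$fraction)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$seed), colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "fraction of high-pigment states",
                  title = sprintf("In-silico overexpression of %s (p = %.3g)",
                                  object$node, object$p_value)) +
    ggplot2::theme_minimal()
}

#' PCA plot of ensemble states
#'
#' Leading principal components of the z-normalised steady states,
#' coloured by a chosen node's z-score (or pigmentation score).
#'
#' @param object A `state_pca` from [pca_projection()].
#' @param colour_by Optional numeric vector to colour points by.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.state_pca <- function(object, colour_by = NULL, ...) {
  df <- object$coordinates
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(colour_by)) {
    df$colour <- colour_by
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                          colour = .data$colour)) +
      ggplot2::scale_colour_gradient2(low = "#2166AC", mid = "grey85",
                                      high = "#B2182B", name = NULL)
  }
  p + ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
      title = "Ensemble steady states, principal components") +
    ggplot2::theme_minimal()
}
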