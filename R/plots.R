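#' Plot the z-scored versatility distribution with the hub threshold
#'
#' Mirrors the standard diagnostic for hub detection: the distribution of
#' z-scored multilayer versatility over nodes, with a dashed line at the
#' hub threshold; hubs fall to its right.
#'
#' @param object an `ml_subject`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot ml_subject
#' @export
autoplot.ml_subject <- function(object, ...) {
  ggplot2::ggplot(object$hub_table,
                  ggplot2::aes(x = .data$z_versatility)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$config$hub_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "z-scored multilayer versatility", y = "nodes",
                  title = "Hub detection",
                  subtitle = paste0(sum(object$hub_table$is_hub),
                                    " hub(s) beyond z = ",
                                    object$config$hub_threshold)) +
    ggplot2::theme_minimal()
}

#' Plot group-level DCI inference
#'
#' Effect size (mean scaled DCI across subjects) against -log10 p per
#' candidate node; the dashed line marks p = 0.05.
#'
#' @param object a `group_result`.
#' @param label_top label this many smallest-p nodes (default 5).
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot group_result
#' @export
autoplot.group_result <- function(object, label_top = 5, ...) {
  df <- tibble::as_tibble(object)
  top <- df[order(df$p_value), ][seq_len(min(label_top, nrow(df))), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect,
                                   y = -log10(.data$p_value))) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::geom_text(data = top,
                       ggplot2::aes(label = .data$label),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = "mean scaled DCI (effect size)",
                  y = expression(-log[10] ~ p),
                  title = "Group connector-hub inference") +
    ggplot2::theme_minimal()
}

#' Heatmap of a supra-adjacency matrix
#'
#' Tile plot of the full multilayer network with gridlines at layer
#' boundaries; off-diagonal blocks hold the interlayer (between-frequency)
#' connections.
#'
#' @param supra a `supra_adjacency`.
#' @return A ggplot.
#' @export
plot_supra <- function(supra) {
  stopifnot(inherits(supra, "supra_adjacency"))
  N <- supra$n_nodes; B <- supra$n_layers
  df <- tidyr::expand_grid(row = seq_len(N * B), col = seq_len(N * B))
  df$weight <- as.numeric(supra$mat[cbind(df$row, df$col)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::geom_hline(yintercept = N * seq_len(B - 1) + 0.5,
                        colour = "white", linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = N * seq_len(B - 1) + 0.5,
                        colour = "white", linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "weight",
                  title = paste0("Supra-adjacency (", N, " nodes x ", B,
                                 " layers)")) +
    ggplot2::theme_minimal()
}
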