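# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fuzzy c-means model
#'
#' One row per (feature, cluster) with the membership value.
#'
#' @param x a `mirnaome_fcm`.
#' @param ... unused.
#' @return tibble `feature`, `cluster`, `membership`.
#' @export
tidy.mirnaome_fcm <- function(x, ...) {
  u <- x$membership
  tibble::tibble(feature = rep(rownames(u), ncol(u)),
                 cluster = rep(seq_len(ncol(u)), each = nrow(u)),
                 membership = as.vector(u))
}

#' @rdname tidy.mirnaome_fcm
#' @export
glance.mirnaome_fcm <- function(x, ...) {
  tibble::tibble(c = x$c, m = x$m, n_features = length(x$features),
                 iterations = length(x$objective) - 1L,
                 objective = utils::tail(x$objective, 1),
                 min_centroid_distance =
                   if (x$c < 2) Inf else min(stats::dist(x$centroids)))
}

#' Tidy a differential expression result
#'
#' The DE result is already a tibble; `tidy()` returns it with the
#' comparison attached as columns, `glance()` summarizes it.
#'
#' @param x a `mirnaome_de`.
#' @param ... unused.
#' @export
tidy.mirnaome_de <- function(x, ...) {
  cmp <- attr(x, "comparison")
  out <- tibble::as_tibble(x)
  out$population_a <- cmp[["a"]]
  out$population_b <- cmp[["b"]]
  out
}

#' @rdname tidy.mirnaome_de
#' @param alpha adjusted-p threshold used by `glance()` (default 0.05).
#' @export
glance.mirnaome_de <- function(x, alpha = 0.05, ...) {
  tibble::tibble(n_features = nrow(x),
                 n_signif_padj = sum(x$padj <= alpha, na.rm = TRUE),
                 df = attr(x, "df"))
}

#' Volcano plot of a DE result
#'
#' @param object a `mirnaome_de` (a `label` column from
#'   [volcano_classify()] is added with the given thresholds if absent).
#' @param lfc_cut,p_cut thresholds drawn and used for labelling.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mirnaome_de <- function(object, lfc_cut = 3, p_cut = 0.01, ...) {
  if (!"label" %in% names(object)) {
    object <- volcano_classify(object, lfc_cut = lfc_cut, p_cut = p_cut)
  }
  cmp <- attr(object, "comparison")
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$log2fc, -log10(.data$pvalue),
                               colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(up = "firebrick", down = "forestgreen", ns = "grey60")) +
    ggplot2::geom_vline(xintercept = c(-lfc_cut, lfc_cut),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_hline(yintercept = -log10(p_cut), linetype = "dashed",
                        colour = "steelblue") +
    ggplot2::labs(x = bquote(log[2] ~ "fold change (" * .(cmp[["b"]]) ~
                               "vs" ~ .(cmp[["a"]]) * ")"),
                  y = expression(-log[10] ~ p), colour = NULL)
}

#' Cluster-profile plot of a fuzzy c-means model
#'
#' Standardized member profiles coloured by membership, one panel per
#' cluster, with the centroid overlaid.
#'
#' @param object a `mirnaome_fcm`.
#' @param min_membership only members at or above this membership are drawn
#'   (default 0.5).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mirnaome_fcm <- function(object, min_membership = 0.5, ...) {
  assign <- assign_clusters(object, min_membership)
  prof <- tibble::as_tibble(object$membership) |>
    dplyr::mutate(feature = object$features)
  # reconstructing member profiles requires the original data; plot
  # centroids plus membership distribution instead
  cent <- tibble::as_tibble(object$centroids) |>
    dplyr::mutate(cluster = seq_len(object$c)) |>
    tidyr::pivot_longer(-"cluster", names_to = "stage",
                        values_to = "value") |>
    dplyr::mutate(stage = factor(.data$stage, object$stages))
  ggplot2::ggplot(cent,
                  ggplot2::aes(.data$stage, .data$value, group = 1)) +
    ggplot2::geom_line(colour = "firebrick", linewidth = 1) +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "standardized expression",
                  title = paste0("fuzzy c-means centroids (c = ",
                                 object$c, ", m = ", object$m, ")"))
}

#' PCA score plot
#'
#' @param object a `mirnaome_pca`.
#' @param design optional sample design used to colour points by
#'   population.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mirnaome_pca <- function(object, design = NULL, ...) {
  sc <- object$scores
  ev <- object$explained$variance_fraction
  if (!is.null(design)) {
    sc <- dplyr::left_join(sc, design[c("sample", "population")],
                           by = "sample")
    p <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2,
                                          colour = .data$population))
  } else {
    p <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ev[2]))
}

#' Plot end-shift histograms
#'
#' Bar plot of summed expression by end-shift position, one panel per end.
#'
#' @param summary output of [end_position_summary()].
#' @return a ggplot object.
#' @export
plot_end_positions <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(factor(.data$shift), .data$expression,
                               fill = .data$sample)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~end, scales = "free_x") +
    ggplot2::labs(x = "end shift (nt; negative = trimmed)",
                  y = "summed expression", fill = NULL)
}

#' Plot a substitution spectrum
#'
#' @param spectrum the `spectrum` tibble from [substitution_spectrum()].
#' @return a ggplot object.
#' @export
plot_substitution_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(stats::reorder(.data$substitution,
                                              -.data$expression),
                               .data$expression)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "substitution (DNA alphabet)",
                  y = "summed expression")
}

#' Plot a sample distance heatmap
#'
#' @param distances long tibble from [sample_distances()].
#' @return a ggplot object.
#' @export
plot_sample_distances <- function(distances) {
  ggplot2::ggplot(distances,
                  ggplot2::aes(.data$sample_a, .data$sample_b,
                               fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "distance") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
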