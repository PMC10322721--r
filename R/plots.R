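#' Plot a receptor PCA fit
#'
#' Scree panel (variance fraction per PC) beside the receptor-space
#' projection of all areas onto PC1/PC2.
#'
#' @param object A [receptor_pca()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.receptor_pca <- function(object, ...) {
  rs <- receptor_space(object)
  ggplot2::ggplot(rs, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%% variance)",
                              100 * object$variance_fraction[1]),
                  y = sprintf("PC2 (%.1f%% variance)",
                              100 * object$variance_fraction[2]),
                  title = "Receptor space") +
    ggplot2::theme_minimal()
}

#' Scree plot of gradient variance fractions
#'
#' @param fit A [receptor_pca()] fit.
#' @param max_pc Number of PCs shown (default 10).
#' @return A ggplot object.
#' @export
plot_scree <- function(fit, max_pc = 10) {
  k <- min(max_pc, length(fit$variance_fraction))
  df <- tibble::tibble(pc = factor(seq_len(k)),
                       variance_fraction = fit$variance_fraction[seq_len(k)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc,
                                   y = .data$variance_fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "principal component", y = "variance fraction") +
    ggplot2::theme_minimal()
}

#' Polar receptor fingerprint
#'
#' The conventional polar rendering of one area's receptor densities.
#'
#' @param fp A [fingerprint()] tibble.
#' @return A ggplot object.
#' @export
plot_fingerprint <- function(fp) {
  ggplot2::ggplot(fp, ggplot2::aes(x = .data$receptor, y = .data$density,
                                   group = 1)) +
    ggplot2::geom_polygon(fill = "steelblue", alpha = 0.4,
                          colour = "steelblue") +
    ggplot2::coord_polar() +
    ggplot2::labs(title = attr(fp, "area_id"), x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Dice embedding profile
#'
#' Dice coefficient per gradient percentile bin with the scalar embedding
#' position marked.
#'
#' @param object A [dice_embedding()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dice_embedding <- function(object, ...) {
  pos <- attr(object, "position")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$bin, y = .data$dice)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = pos, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "gradient percentile bin", y = "Dice coefficient",
                  subtitle = sprintf("embedding position %.2f", pos)) +
    ggplot2::theme_minimal()
}

#' Plot per-network gradient distributions
#'
#' Violin-plus-point summary of a gradient's values within each cognitive
#' network.
#'
#' @param summary_result Output of [network_summary()].
#' @return A ggplot object.
#' @export
plot_network_summary <- function(summary_result) {
  ggplot2::ggplot(summary_result$distribution,
                  ggplot2::aes(x = .data$network, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_point(data = summary_result$summary,
                        ggplot2::aes(y = .data$mean), colour = "firebrick",
                        size = 2) +
    ggplot2::labs(x = NULL, y = "gradient score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
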