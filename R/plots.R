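# ggplot2 views of the main result types. These return plot objects; the
# pipeline's report stage saves them only on request.

#' Plot lipid pool-fraction trajectories
#'
#' Replicate-mean fractions of the lipid pool held in phospholipids (solid)
#' and storage lipids (dash-dot) over time, one panel-free line pair per
#' C/N condition — the remodeling crossover view.
#'
#' @param fractions Per-sample fractions from [pool_fractions()].
#' @param design Design table.
#' @return A ggplot object.
#' @export
plot_pool_fractions <- function(fractions, design) {
  check_design(design)
  df <- fractions %>%
    dplyr::left_join(dplyr::select(design, "sample_id", "condition", "timepoint"),
                     by = "sample_id") %>%
    dplyr::group_by(.data$condition, .data$timepoint) %>%
    dplyr::summarise(phospholipid = mean(.data$frac_phospholipid),
                     storage = mean(.data$frac_storage), .groups = "drop") %>%
    tidyr::pivot_longer(c("phospholipid", "storage"),
                        names_to = "pool", values_to = "fraction")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$fraction,
                                   colour = factor(.data$condition),
                                   linetype = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_linetype_manual(values = c(phospholipid = "solid",
                                              storage = "dotdash")) +
    ggplot2::labs(x = "time (h)", y = "fraction of lipid pool",
                  colour = "C/N", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Horizontal bar chart of pathway up/down (or TAG +/-) fractions
#'
#' Diverging horizontal bars, one per pathway, ranked as in the fraction
#' table: most up-regulated (or TAG-positive) pathways on top.
#'
#' @param fractions A pathway fraction table from [geneset_fractions()]
#'   (`frac_up`/`frac_down`) or [pathway_tag_fractions()]
#'   (`frac_pos`/`frac_neg`).
#' @return A ggplot object.
#' @export
plot_pathway_fractions <- function(fractions) {
  up_col <- intersect(c("frac_up", "frac_pos"), names(fractions))[1]
  down_col <- intersect(c("frac_down", "frac_neg"), names(fractions))[1]
  if (is.na(up_col) || is.na(down_col)) {
    abort("expected frac_up/frac_down or frac_pos/frac_neg columns")
  }
  df <- fractions %>%
    dplyr::mutate(pathway = stats::reorder(.data$pathway, -.data$sort_rank)) %>%
    tidyr::pivot_longer(dplyr::all_of(c(up_col, down_col)),
                        names_to = "direction", values_to = "fraction") %>%
    dplyr::mutate(fraction = ifelse(.data$direction == down_col,
                                    -.data$fraction, .data$fraction))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$pathway,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(
      values = stats::setNames(c("#178a3b", "#c0392b"), c(up_col, down_col)),
      labels = stats::setNames(c("up / TAG-positive", "down / TAG-negative"),
                               c(up_col, down_col))) +
    ggplot2::labs(x = "fraction of pathway genes", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' PCA score plot
#'
#' Sample scores on two principal components, colored by C/N condition and
#' shaped by nitrogen state when a design table is supplied — the
#' divergence-over-time view.
#'
#' @param object A `lipomix_pca` object.
#' @param design Optional design table for aesthetics.
#' @param components Two components to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lipomix_pca
#' @export
autoplot.lipomix_pca <- function(object, design = NULL,
                                 components = c("PC1", "PC2"), ...) {
  df <- object$scores
  vf <- stats::setNames(object$variance$variance_fraction, object$variance$component)
  labs <- sprintf("%s (%.1f%%)", components, 100 * vf[components])
  aes <- ggplot2::aes(x = .data[[components[1]]], y = .data[[components[2]]])
  if (!is.null(design)) {
    df <- dplyr::left_join(df, design, by = "sample_id")
    aes <- ggplot2::aes(x = .data[[components[1]]], y = .data[[components[2]]],
                        colour = factor(.data$condition),
                        shape = .data$nitrogen_state)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = labs[1], y = labs[2], colour = "C/N", shape = "N state") +
    ggplot2::theme_minimal()
}

#' Heatmap of the lipid-by-gene correlation clustermap
#'
#' The correlation matrix rendered as tiles with both axes ordered by their
#' dendrograms; annotation strips would be overkill here, cluster boundaries
#' are visible in the block structure.
#'
#' @param corr Correlation matrix from [cross_correlation()].
#' @param biclusters Optional `lipomix_biclusters` supplying axis orders.
#' @return A ggplot object.
#' @export
plot_correlation_map <- function(corr, biclusters = NULL) {
  row_ord <- rownames(corr)
  col_ord <- colnames(corr)
  if (!is.null(biclusters)) {
    row_ord <- rownames(corr)[biclusters$lipid_clusters$hclust$order]
    col_ord <- colnames(corr)[biclusters$gene_clusters$hclust$order]
  }
  df <- matrix_tibble(corr, "lipid_id") %>%
    tidyr::pivot_longer(-"lipid_id", names_to = "gene_id", values_to = "r") %>%
    dplyr::mutate(lipid_id = factor(.data$lipid_id, levels = row_ord),
                  gene_id = factor(.data$gene_id, levels = col_ord))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_id, y = .data$lipid_id,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = "genes", y = "lipids", fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}
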