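# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cluster assignment
#'
#' @param x A `lipomix_clusters` object.
#' @param ... Unused.
#' @return Tibble `item_id`, `cluster_label`, `linkage_height`.
#' @method tidy lipomix_clusters
#' @export
tidy.lipomix_clusters <- function(x, ...) {
  x$assignment
}

#' One-row summary of a cluster assignment
#'
#' @param x A `lipomix_clusters` object.
#' @param ... Unused.
#' @return Tibble with `axis`, `n_items`, `k`, `linkage`, `max_height`.
#' @method glance lipomix_clusters
#' @export
glance.lipomix_clusters <- function(x, ...) {
  tibble::tibble(
    axis = x$axis,
    n_items = nrow(x$assignment),
    k = x$k,
    linkage = x$hclust$method,
    max_height = max(x$hclust$height)
  )
}

#' Tidy PCA scores (and optionally loadings / variance fractions)
#'
#' @param x A `lipomix_pca` object.
#' @param matrix One of `"scores"`, `"loadings"`, `"variance"`.
#' @param ... Unused.
#' @return Tibble of the requested component.
#' @method tidy lipomix_pca
#' @export
tidy.lipomix_pca <- function(x, matrix = "scores", ...) {
  switch(matrix,
         scores = x$scores,
         loadings = x$loadings,
         variance = x$variance,
         abort("matrix must be 'scores', 'loadings' or 'variance'"))
}

#' One-row summary of a PCA
#'
#' @param x A `lipomix_pca` object.
#' @param ... Unused.
#' @return Tibble with sample count, component count and the cumulative
#'   variance fraction of the returned components.
#' @method glance lipomix_pca
#' @export
glance.lipomix_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_components = x$n_components,
    cum_variance = sum(x$variance$variance_fraction[seq_len(x$n_components)])
  )
}

#' Tidy a biclustering result
#'
#' @param x A `lipomix_biclusters` object.
#' @param ... Unused.
#' @return The TAG-sign tibble (`gene_id`, `mean_r_tag`, `sign`,
#'   `multiomic_cluster`).
#' @method tidy lipomix_biclusters
#' @export
tidy.lipomix_biclusters <- function(x, ...) {
  x$tag_signs
}

#' One-row summary of a biclustering
#'
#' @param x A `lipomix_biclusters` object.
#' @param ... Unused.
#' @return Tibble with axis sizes, block counts, and P1/P2 sizes.
#' @method glance lipomix_biclusters
#' @export
glance.lipomix_biclusters <- function(x, ...) {
  tibble::tibble(
    n_lipids = nrow(x$lipid_clusters$assignment),
    n_genes = nrow(x$tag_signs),
    k_lipids = x$k_lipids,
    k_genes = x$k_genes,
    n_p1 = sum(x$tag_signs$multiomic_cluster == "P1"),
    n_p2 = sum(x$tag_signs$multiomic_cluster == "P2")
  )
}
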