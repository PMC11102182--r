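#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of sample expression profiles using Euclidean
#' distance between the columns of a row-scaled matrix, cut into `k` flat
#' clusters. Cluster labels `S1..Sk` follow left-to-right dendrogram order,
#' so the labeling is deterministic given the input.
#'
#' @param scaled Row-scaled wide tibble from [scale_rows()].
#' @param k Number of flat clusters (<= number of samples).
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @return A `lipomix_clusters` object: tibble accessor via [tidy()],
#'   `$assignment` (`item_id`, `cluster_label`, `linkage_height`),
#'   `$hclust`, `$k`, `$axis`.
#' @examples
#' sim <- simulate_transcriptome(make_design(), n_genes = 100, seed = 1)
#' scl <- scale_rows(normalize_counts(sim$counts))
#' tidy(hcluster_samples(scl, k = 5))
#' @export
hcluster_samples <- function(scaled, k = 5, linkage = "complete") {
  m <- omic_matrix(scaled, names(scaled)[1])
  if (k > ncol(m)) abort("k exceeds the number of samples")
  hc <- stats::hclust(stats::dist(t(m), method = "euclidean"), method = linkage)
  new_clusters(hc, k, axis = "samples", prefix = "S")
}

#' Hierarchical clustering of features by correlation distance
#'
#' Clusters feature (gene or lipid) profiles with distance
#' `1 - Pearson r` between rows, complete linkage by default, cut into `k`
#' flat clusters. Invariant to per-feature affine rescaling. Constant rows
#' have no defined correlation and are rejected — drop them first with
#' [scale_rows()].
#'
#' @param scaled Wide tibble of profiles (id column first).
#' @param k Number of flat clusters.
#' @param linkage Agglomeration method.
#' @return A `lipomix_clusters` object with provisional labels `F1..Fk`
#'   (use [label_clusters_by_trend()] for trend-anchored `C1..C3` labels).
#' @export
hcluster_features <- function(scaled, k = 3, linkage = "complete") {
  m <- omic_matrix(scaled, names(scaled)[1])
  if (k > nrow(m)) abort("k exceeds the number of features")
  sds <- apply(m, 1, pop_sd)
  if (any(sds == 0)) {
    abort(paste0("constant feature row(s): ",
                 paste(utils::head(rownames(m)[sds == 0], 5), collapse = ", "),
                 " - drop them with scale_rows() first"))
  }
  d <- stats::as.dist(1 - stats::cor(t(m)))
  hc <- stats::hclust(d, method = linkage)
  new_clusters(hc, k, axis = "features", prefix = "F")
}

new_clusters <- function(hc, k, axis, prefix) {
  idx <- stats::cutree(hc, k = k)
  # relabel cluster indices by first appearance in dendrogram order
  ord <- idx[hc$order]
  remap <- stats::setNames(seq_along(unique(ord)), unique(ord))
  labels <- sprintf("%s%d", prefix, remap[as.character(idx)])
  heights <- cluster_heights(hc, idx)
  structure(
    list(
      assignment = tibble::tibble(
        item_id = names(idx),
        cluster_label = labels,
        linkage_height = unname(heights[idx])
      ),
      hclust = hc, k = k, axis = axis
    ),
    class = "lipomix_clusters"
  )
}

# height at which each flat cluster is complete (max merge height inside it)
cluster_heights <- function(hc, idx) {
  vapply(sort(unique(idx)), function(ci) {
    members <- which(idx == ci)
    if (length(members) == 1) return(0)
    h <- 0
    in_cl <- rep(FALSE, nrow(hc$merge) + 1)
    # walk merges; a merge whose leaves are all in the cluster contributes
    leaf_sets <- vector("list", nrow(hc$merge))
    for (i in seq_len(nrow(hc$merge))) {
      get_leaves <- function(j) if (j < 0) -j else leaf_sets[[j]]
      leaves <- c(get_leaves(hc$merge[i, 1]), get_leaves(hc$merge[i, 2]))
      leaf_sets[[i]] <- leaves
      if (all(idx[leaves] == ci)) h <- max(h, hc$height[i])
    }
    h
  }, numeric(1))
}

#' @export
print.lipomix_clusters <- function(x, ...) {
  cat(sprintf("<lipomix_clusters> %d %s in %d clusters (%s linkage)\n",
              nrow(x$assignment), x$axis, x$k, x$hclust$method))
  print(dplyr::count(x$assignment, .data$cluster_label))
  invisible(x)
}

#' Relabel feature clusters by their nitrogen-response trend
#'
#' Anchors arbitrary flat-cluster labels to biology: for each cluster, the
#' mean over member genes of (mean normalized expression in starved samples
#' minus mean in replete samples) is computed, clusters are ordered by that
#' trend, and labeled `C1` (most negative, down under starvation) through
#' `Ck` (most positive, up under starvation); with `k = 3` the middle,
#' near-zero cluster is `C2`. Ties beyond `tol` are broken by cluster size
#' (larger first) then lexically, so the labeling is stable across runs.
#'
#' @param clusters `lipomix_clusters` from [hcluster_features()].
#' @param normalized Normalized expression tibble ([normalize_counts()]).
#' @param design Design table with `nitrogen_state`.
#' @param tol Tolerance below which two cluster trends count as tied.
#' @return The `lipomix_clusters` object with `C*` labels and a
#'   `$trend` tibble (`cluster_label`, `trend`, `n`).
#' @export
label_clusters_by_trend <- function(clusters, normalized, design, tol = 1e-9) {
  check_design(design)
  m <- omic_matrix(normalized, names(normalized)[1])
  starved <- design$sample_id[design$nitrogen_state == "starved"]
  replete <- design$sample_id[design$nitrogen_state == "replete"]
  starved <- intersect(starved, colnames(m))
  replete <- intersect(replete, colnames(m))
  if (length(starved) == 0 || length(replete) == 0) {
    abort("design must contain both replete and starved samples")
  }
  gene_trend <- rowMeans(m[, starved, drop = FALSE]) -
    rowMeans(m[, replete, drop = FALSE])

  assign <- clusters$assignment
  per_cluster <- assign %>%
    dplyr::mutate(trend = unname(gene_trend[.data$item_id])) %>%
    dplyr::group_by(.data$cluster_label) %>%
    dplyr::summarise(trend = mean(.data$trend), n = dplyr::n(), .groups = "drop")

  # order by trend; near-ties resolved by size then label
  per_cluster <- per_cluster %>%
    dplyr::mutate(trend_r = round(.data$trend / max(tol, 1e-300)) * max(tol, 1e-300)) %>%
    dplyr::arrange(.data$trend_r, dplyr::desc(.data$n), .data$cluster_label) %>%
    dplyr::mutate(new_label = sprintf("C%d", dplyr::row_number()))

  remap <- stats::setNames(per_cluster$new_label, per_cluster$cluster_label)
  clusters$assignment$cluster_label <- unname(remap[assign$cluster_label])
  clusters$trend <- per_cluster %>%
    dplyr::transmute(cluster_label = .data$new_label, .data$trend, .data$n) %>%
    dplyr::arrange(.data$cluster_label)
  clusters
}

#' PCA ordination of samples
#'
#' Principal component analysis of sample profiles: the row-scaled matrix is
#' transposed so samples are observations, column-centered, and decomposed
#' by SVD. Variance fractions are non-increasing and sum to 1 over the full
#' rank. Component signs are fixed by making the largest-magnitude loading
#' of each component positive, so results are reproducible across BLAS
#' implementations.
#'
#' @param scaled Row-scaled wide tibble ([scale_rows()]).
#' @param n_components Number of components to return (<= min(genes, samples)).
#' @return A `lipomix_pca` object: `$scores` (tibble `sample_id`, `PC1..`),
#'   `$loadings` (tibble id + `PC1..`), `$variance` (tibble `component`,
#'   `variance_fraction` over the full rank), `$n_components`.
#' @examples
#' sim <- simulate_transcriptome(make_design(), n_genes = 100, seed = 1)
#' pca <- pca_samples(scale_rows(normalize_counts(sim$counts)))
#' glance(pca)
#' @export
pca_samples <- function(scaled, n_components = 2) {
  id_col <- names(scaled)[1]
  m <- omic_matrix(scaled, id_col)
  x <- t(m) # samples x genes
  if (n_components > min(dim(x))) {
    abort("n_components exceeds min(n_genes, n_samples)")
  }
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  keep <- seq_len(n_components)
  flip <- vapply(keep, function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], n_components),
                  2, flip, "*")
  loadings <- sweep(sv$v[, keep, drop = FALSE], 2, flip, "*")
  pcs <- sprintf("PC%d", keep)
  ev <- sv$d^2
  structure(
    list(
      scores = tibble::as_tibble(stats::setNames(as.data.frame(scores), pcs)) %>%
        dplyr::mutate(sample_id = rownames(x), .before = 1),
      loadings = tibble::as_tibble(stats::setNames(as.data.frame(loadings), pcs)) %>%
        dplyr::mutate(!!id_col := rownames(m), .before = 1),
      variance = tibble::tibble(component = sprintf("PC%d", seq_along(ev)),
                                variance_fraction = ev / sum(ev)),
      n_components = n_components
    ),
    class = "lipomix_pca"
  )
}

#' @export
print.lipomix_pca <- function(x, ...) {
  cat(sprintf("<lipomix_pca> %d samples, %d components\n",
              nrow(x$scores), x$n_components))
  vf <- x$variance$variance_fraction[seq_len(x$n_components)]
  cat("variance fractions:", paste(sprintf("%.3f", vf), collapse = " "), "\n")
  invisible(x)
}

#' Per-pathway fractions of up- and down-regulated genes
#'
#' For every pathway class, the fraction of its member genes that are up- or
#' down-regulated in a differential-expression set:
#' `frac_up = |up members| / |members|` and analogously for down. Pathways
#' are ranked with the highest up-fraction at the top and the highest
#' down-fraction at the bottom (sorted by `frac_up - frac_down`, ties broken
#' by pathway name), the horizontal-bar-chart convention.
#'
#' @param de Differential-expression set from [de_filter()]
#'   (`gene_id`, `direction`).
#' @param annotation Pathway annotation (`gene_id`, `pathway`).
#' @param universe Optional tibble `pathway`, `n_genes` giving the member
#'   universe per pathway; defaults to counts derived from `annotation`.
#'   Every annotated pathway must be present with a count at least its
#'   observed membership.
#' @return Tibble `pathway`, `n_genes`, `frac_up`, `frac_down`, `sort_rank`.
#' @export
geneset_fractions <- function(de, annotation, universe = NULL) {
  stopifnot(all(c("gene_id", "pathway") %in% names(annotation)))
  members <- annotation %>%
    dplyr::distinct(.data$gene_id, .data$pathway)
  counts <- members %>% dplyr::count(.data$pathway, name = "n_genes")
  if (is.null(universe)) {
    universe <- counts
  } else {
    missing_pw <- setdiff(counts$pathway, universe$pathway)
    if (length(missing_pw) > 0) {
      abort(paste0("pathway(s) absent from universe: ",
                   paste(missing_pw, collapse = ", ")))
    }
    short <- dplyr::left_join(counts, universe, by = "pathway",
                              suffix = c("_obs", "")) %>%
      dplyr::filter(.data$n_genes < .data$n_genes_obs)
    if (nrow(short) > 0) {
      abort(paste0("universe smaller than observed membership for: ",
                   paste(short$pathway, collapse = ", ")))
    }
  }
  hits <- members %>%
    dplyr::inner_join(de, by = "gene_id") %>%
    dplyr::count(.data$pathway, .data$direction) %>%
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       values_fill = 0)
  for (col in c("up", "down")) {
    if (!col %in% names(hits)) hits[[col]] <- 0L
  }
  universe %>%
    dplyr::filter(.data$n_genes > 0) %>%
    dplyr::left_join(hits, by = "pathway") %>%
    dplyr::mutate(up = dplyr::coalesce(.data$up, 0L),
                  down = dplyr::coalesce(.data$down, 0L),
                  frac_up = .data$up / .data$n_genes,
                  frac_down = .data$down / .data$n_genes) %>%
    dplyr::arrange(dplyr::desc(.data$frac_up - .data$frac_down), .data$pathway) %>%
    dplyr::mutate(sort_rank = dplyr::row_number()) %>%
    dplyr::select("pathway", "n_genes", "frac_up", "frac_down", "sort_rank")
}
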