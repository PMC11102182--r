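#' Align lipid and transcript profiles on shared condition-timepoint cells
#'
#' Collapses both omic layers to replicate means per (condition, timepoint)
#' cell and restricts them to the cells present in both, yielding two
#' matrices over one identical, ordered cell axis — the profiles the
#' cross-omic correlations are computed over. Replicate means suppress
#' within-cell noise so the correlation compares trajectory shapes across
#' media conditions and time. With `per_replicate = TRUE` the shared
#' individual samples are used instead.
#'
#' @param quant Lipid quant table ([quantify()]): `species_id`,
#'   `lipid_class` + sample columns.
#' @param normalized Normalized expression tibble ([normalize_counts()]).
#' @param design Design table covering the samples of both tables.
#' @param per_replicate Pair individual shared samples instead of replicate
#'   means.
#' @return A list (`lipomix_profiles`): `$lipids` and `$genes` (matrices,
#'   features x cells), `$cells` (tibble `cell_id`, `condition`,
#'   `timepoint`). Errors if fewer than 3 shared cells remain (Pearson r is
#'   meaningless below that).
#' @examples
#' design <- make_design()
#' tr <- simulate_transcriptome(design, n_genes = 60, seed = 1)
#' lp <- simulate_lipidome(design, seed = 1)
#' quant <- quantify(lp$intensities, lp$cocktail)
#' prof <- align_profiles(quant, normalize_counts(tr$counts), design)
#' ncol(prof$lipids) # 11 cells for the default design
#' @export
align_profiles <- function(quant, normalized, design, per_replicate = FALSE) {
  check_design(design)
  l_mat <- omic_matrix(quant, names(quant)[1],
                       intersect(c("lipid_class", "is_internal_standard"), names(quant)))
  g_mat <- omic_matrix(normalized, names(normalized)[1])

  if (per_replicate) {
    shared <- intersect(colnames(l_mat), colnames(g_mat))
    shared <- design$sample_id[design$sample_id %in% shared] # design order
    if (length(shared) < 3) abort("fewer than 3 shared samples")
    cells <- design %>%
      dplyr::filter(.data$sample_id %in% shared) %>%
      dplyr::transmute(cell_id = .data$sample_id, .data$condition, .data$timepoint)
    out <- list(lipids = l_mat[, shared, drop = FALSE],
                genes = g_mat[, shared, drop = FALSE], cells = cells)
    return(structure(out, class = "lipomix_profiles"))
  }

  cell_means <- function(m) {
    d <- design %>% dplyr::filter(.data$sample_id %in% colnames(m))
    cells <- d %>%
      dplyr::distinct(.data$condition, .data$timepoint) %>%
      dplyr::arrange(.data$condition, .data$timepoint) %>%
      dplyr::mutate(cell_id = cell_id(.data$condition, .data$timepoint))
    mm <- vapply(seq_len(nrow(cells)), function(i) {
      ids <- d$sample_id[d$condition == cells$condition[i] &
                           d$timepoint == cells$timepoint[i]]
      rowMeans(m[, ids, drop = FALSE])
    }, numeric(nrow(m)))
    colnames(mm) <- cells$cell_id
    list(m = mm, cells = cells)
  }
  lip <- cell_means(l_mat)
  gen <- cell_means(g_mat)
  shared <- intersect(lip$cells$cell_id, gen$cells$cell_id)
  if (length(shared) < 3) {
    abort(sprintf("only %d shared condition-timepoint cells; need >= 3",
                  length(shared)))
  }
  cells <- lip$cells %>%
    dplyr::filter(.data$cell_id %in% shared) %>%
    dplyr::select("cell_id", "condition", "timepoint")
  structure(
    list(lipids = lip$m[, cells$cell_id, drop = FALSE],
         genes = gen$m[, cells$cell_id, drop = FALSE],
         cells = cells),
    class = "lipomix_profiles"
  )
}

#' Lipid-by-gene Pearson correlation matrix
#'
#' Pearson correlation between every lipid profile and every gene profile
#' over the aligned condition-timepoint cells: the value matrix of the
#' multi-omic clustermap. Profiles that are constant across cells have no
#' defined correlation; their entries are `NA` and a warning names them.
#'
#' @param profiles Aligned profiles from [align_profiles()], or a list with
#'   matrices `lipids` and `genes` sharing a column axis.
#' @return Numeric matrix, lipids x genes, entries in `[-1, 1]`.
#' @export
cross_correlation <- function(profiles) {
  l <- profiles$lipids
  g <- profiles$genes
  if (ncol(l) != ncol(g)) abort("profile matrices must share their cell axis")
  const_l <- apply(l, 1, pop_sd) == 0
  const_g <- apply(g, 1, pop_sd) == 0
  if (any(const_l) || any(const_g)) {
    warn(paste0("constant profile(s), correlations set NA: ",
                paste(c(rownames(l)[const_l], rownames(g)[const_g]),
                      collapse = ", ")))
  }
  r <- suppressWarnings(stats::cor(t(l), t(g)))
  r[const_l, ] <- NA_real_
  r[, const_g] <- NA_real_
  r
}

#' Bicluster the correlation matrix and label gene clusters by TAG sign
#'
#' Both axes of the lipid-by-gene correlation matrix are clustered
#' hierarchically, treating each row (lipid) and column (gene) of
#' correlations as a feature vector under Euclidean distance with complete
#' linkage, and cut into `k_lipids` x `k_genes` blocks. Each gene's
#' `mean_r_tag` — its mean correlation over the TAG species — determines its
#' sign (`positive` iff `mean_r_tag > 0`); gene clusters are labeled by
#' their mean `mean_r_tag`: lowest cluster `P1` (anti-correlated with TAG),
#' highest `P2` (TAG-positive), remainder `P3` (and up, for larger k).
#'
#' @param corr Correlation matrix from [cross_correlation()].
#' @param k_lipids,k_genes Flat cluster counts for the two axes.
#' @param tag_ids Lipid ids (rows of `corr`) forming the TAG reference set.
#' @param linkage Agglomeration method.
#' @return A `lipomix_biclusters` object: `$tag_signs` (tibble `gene_id`,
#'   `mean_r_tag`, `sign`, `multiomic_cluster`), `$gene_clusters` and
#'   `$lipid_clusters` (`lipomix_clusters`), plus the two hclust trees.
#' @examples
#' design <- make_design()
#' tr <- simulate_transcriptome(design, n_genes = 60, seed = 1)
#' lp <- simulate_lipidome(design, seed = 1)
#' prof <- align_profiles(quantify(lp$intensities, lp$cocktail),
#'                        normalize_counts(tr$counts), design)
#' r <- cross_correlation(prof)
#' bic <- bicluster_and_label(r, tag_ids = grep("^TAG", rownames(r), value = TRUE))
#' head(bic$tag_signs)
#' @export
bicluster_and_label <- function(corr, k_lipids = 3, k_genes = 3, tag_ids,
                                linkage = "complete") {
  if (missing(tag_ids) || length(tag_ids) == 0) {
    abort("tag_ids must name at least one lipid row")
  }
  missing_tag <- setdiff(tag_ids, rownames(corr))
  if (length(missing_tag) > 0) {
    abort(paste0("tag_ids absent from correlation matrix: ",
                 paste(missing_tag, collapse = ", ")))
  }
  lipid_hc <- stats::hclust(stats::dist(corr), method = linkage)
  gene_hc <- stats::hclust(stats::dist(t(corr)), method = linkage)
  lipid_cl <- new_clusters(lipid_hc, k_lipids, axis = "lipids", prefix = "L")
  gene_cl <- new_clusters(gene_hc, k_genes, axis = "genes", prefix = "G")

  mean_r_tag <- colMeans(corr[tag_ids, , drop = FALSE])
  signs <- tibble::tibble(
    gene_id = colnames(corr),
    mean_r_tag = unname(mean_r_tag),
    sign = ifelse(mean_r_tag > 0, "positive", "negative")
  )

  cluster_means <- gene_cl$assignment %>%
    dplyr::left_join(signs, by = c(item_id = "gene_id")) %>%
    dplyr::group_by(.data$cluster_label) %>%
    dplyr::summarise(m = mean(.data$mean_r_tag), n = dplyr::n(), .groups = "drop")
  # lowest mean -> P1, highest -> P2, remainder P3.. in ascending order
  ord <- cluster_means %>%
    dplyr::arrange(.data$m, dplyr::desc(.data$n), .data$cluster_label)
  p_labels <- character(nrow(ord))
  p_labels[1] <- "P1"
  p_labels[nrow(ord)] <- "P2"
  if (nrow(ord) > 2) {
    p_labels[seq(2, nrow(ord) - 1)] <- sprintf("P%d", seq(3, nrow(ord)))
  }
  remap <- stats::setNames(p_labels, ord$cluster_label)
  gene_cl$assignment$cluster_label <- unname(remap[gene_cl$assignment$cluster_label])

  signs <- signs %>%
    dplyr::left_join(dplyr::rename(gene_cl$assignment,
                                   gene_id = "item_id",
                                   multiomic_cluster = "cluster_label"),
                     by = "gene_id") %>%
    dplyr::select("gene_id", "mean_r_tag", "sign", "multiomic_cluster")

  structure(
    list(tag_signs = signs, gene_clusters = gene_cl, lipid_clusters = lipid_cl,
         k_lipids = k_lipids, k_genes = k_genes, tag_ids = tag_ids),
    class = "lipomix_biclusters"
  )
}

#' @export
print.lipomix_biclusters <- function(x, ...) {
  cat(sprintf("<lipomix_biclusters> %d lipids x %d genes, %dx%d blocks\n",
              nrow(x$lipid_clusters$assignment), nrow(x$tag_signs),
              x$k_lipids, x$k_genes))
  print(dplyr::count(x$tag_signs, .data$multiomic_cluster, .data$sign))
  invisible(x)
}

#' Per-pathway fractions of TAG-positive and TAG-negative genes
#'
#' Restricts the TAG-sign table to genes carrying a reaction/pathway
#' annotation and computes, per pathway, the fraction of member genes
#' positively and negatively correlated with TAG levels
#' (`frac_pos + frac_neg = 1`). Pathways with `frac_pos > 0.5` — candidate
#' drivers of storage-lipid accumulation — are flagged. Sorted with the most
#' TAG-positive pathways on top (ties by name).
#'
#' @param tag_signs TAG-sign table from [bicluster_and_label()].
#' @param annotation Reaction annotation (`gene_id`, `pathway`); genes
#'   without annotation are excluded.
#' @return Tibble `pathway`, `n_genes`, `frac_pos`, `frac_neg`,
#'   `majority_positive`, `sort_rank`.
#' @export
pathway_tag_fractions <- function(tag_signs, annotation) {
  stopifnot(all(c("gene_id", "pathway") %in% names(annotation)))
  annotation %>%
    dplyr::distinct(.data$gene_id, .data$pathway) %>%
    dplyr::inner_join(tag_signs, by = "gene_id") %>%
    dplyr::group_by(.data$pathway) %>%
    dplyr::summarise(n_genes = dplyr::n(),
                     frac_pos = mean(.data$sign == "positive"),
                     frac_neg = mean(.data$sign == "negative"),
                     .groups = "drop") %>%
    dplyr::mutate(majority_positive = .data$frac_pos > 0.5) %>%
    dplyr::arrange(dplyr::desc(.data$frac_pos), .data$pathway) %>%
    dplyr::mutate(sort_rank = dplyr::row_number())
}

#' Contingency of transcript-only vs multi-omic gene clusters
#'
#' Cross-tabulates each gene's transcript-clustering identity (C1-C3) against
#' its multi-omic clustermap identity (P1-P3). Genes present in only one
#' labeling are excluded from the table body and reported in the `unshared`
#' attribute. Marginals equal cluster sizes over the shared gene universe.
#'
#' @param rna_clusters `lipomix_clusters` from [hcluster_features()] (after
#'   [label_clusters_by_trend()]), or a tibble `item_id`, `cluster_label`.
#' @param tag_signs TAG-sign table from [bicluster_and_label()].
#' @return Tibble `rna_cluster`, `multiomic_cluster`, `n` (complete grid),
#'   with attribute `unshared` = c(rna_only, multiomic_only).
#' @export
cluster_overlap <- function(rna_clusters, tag_signs) {
  rna <- if (inherits(rna_clusters, "lipomix_clusters")) {
    rna_clusters$assignment
  } else {
    rna_clusters
  }
  stopifnot(all(c("item_id", "cluster_label") %in% names(rna)))
  shared <- intersect(rna$item_id, tag_signs$gene_id)
  if (length(shared) == 0) abort("no shared genes between the two labelings")
  body <- dplyr::inner_join(
    dplyr::transmute(rna, gene_id = .data$item_id, rna_cluster = .data$cluster_label),
    dplyr::select(tag_signs, "gene_id", multiomic_cluster = "multiomic_cluster"),
    by = "gene_id"
  ) %>%
    dplyr::count(.data$rna_cluster, .data$multiomic_cluster) %>%
    tidyr::complete(.data$rna_cluster, .data$multiomic_cluster,
                    fill = list(n = 0L))
  attr(body, "unshared") <- c(rna_only = length(setdiff(rna$item_id, shared)),
                              multiomic_only = length(setdiff(tag_signs$gene_id, shared)))
  body
}

#' Reaction color map for pathway-diagram export
#'
#' Projects gene TAG-correlation signs onto genome-scale-model reactions:
#' each reaction's sign is the sign of the mean `mean_r_tag` over its mapped
#' genes — `green` for positive (moves with storage-lipid accumulation),
#' `red` for negative, `neutral` inside the `|mean| <= neutral_eps` band
#' (symmetric conflicts with mean 0 are neutral). Reactions in the mapping
#' whose genes all lack a sign are omitted with a warning.
#'
#' @param tag_signs TAG-sign table from [bicluster_and_label()].
#' @param gene_to_reaction Tibble `gene_id`, `reaction_id`.
#' @param neutral_eps Half-width of the neutral band on mean `mean_r_tag`.
#' @return Tibble `reaction_id`, `mean_r_tag`, `correlation_sign`
#'   (`positive`/`negative`/`neutral`), `color` (`green`/`red`/`neutral`).
#' @seealso [write_reaction_colors()] for the flat JSON export.
#' @export
reaction_color_map <- function(tag_signs, gene_to_reaction, neutral_eps = 0) {
  stopifnot(all(c("gene_id", "reaction_id") %in% names(gene_to_reaction)))
  if (neutral_eps < 0) abort("neutral_eps must be >= 0")
  mapped <- gene_to_reaction %>%
    dplyr::distinct(.data$gene_id, .data$reaction_id)
  unmapped <- setdiff(mapped$reaction_id,
                      mapped$reaction_id[mapped$gene_id %in% tag_signs$gene_id])
  if (length(unmapped) > 0) {
    warn(paste0("reaction(s) without any scored gene omitted: ",
                paste(utils::head(unmapped, 5), collapse = ", "),
                if (length(unmapped) > 5) ", ..." else ""))
  }
  mapped %>%
    dplyr::inner_join(tag_signs, by = "gene_id") %>%
    dplyr::group_by(.data$reaction_id) %>%
    dplyr::summarise(mean_r_tag = mean(.data$mean_r_tag), .groups = "drop") %>%
    dplyr::mutate(
      correlation_sign = dplyr::case_when(
        .data$mean_r_tag > neutral_eps ~ "positive",
        .data$mean_r_tag < -neutral_eps ~ "negative",
        TRUE ~ "neutral"
      ),
      color = dplyr::recode(.data$correlation_sign,
                            positive = "green", negative = "red",
                            neutral = "neutral")
    )
}
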