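suppressMessages({
  int_norm <- normalize_counts(small_transcriptome$counts)
  int_quant <- quantify(small_lipidome$intensities, small_lipidome$cocktail)
  int_prof <- align_profiles(int_quant, int_norm, default_design)
})

test_that("profile alignment yields the 11 shared cells in a fixed order", {
  expect_equal(ncol(int_prof$lipids), 11) # 3 + 4 + 4
  expect_equal(colnames(int_prof$lipids), colnames(int_prof$genes))
  expect_equal(int_prof$cells$cell_id, colnames(int_prof$lipids))
  # permuting sample columns changes nothing
  set.seed(8)
  perm <- c(1, sample(2:ncol(int_quant)))
  prof2 <- align_profiles(int_quant[, perm], int_norm, default_design)
  expect_equal(prof2$lipids, int_prof$lipids)
  # a cell missing from one omic is dropped from both
  drop_ids <- default_design$sample_id[default_design$condition == 100 &
                                         default_design$timepoint == 88]
  prof3 <- align_profiles(int_quant[, setdiff(names(int_quant), drop_ids)],
                          int_norm, default_design)
  expect_equal(ncol(prof3$lipids), 10)
  expect_equal(colnames(prof3$lipids), colnames(prof3$genes))
  # fewer than 3 shared cells is an error
  keep <- default_design$sample_id[default_design$timepoint == 8 &
                                     default_design$condition %in% c(5, 100)]
  expect_error(align_profiles(int_quant[, c("species_id", "lipid_class", keep)],
                              int_norm, default_design),
               "3")
})

test_that("cross correlation matches a brute-force Pearson oracle", {
  set.seed(42)
  n_pairs <- 100
  l <- matrix(rnorm(n_pairs * 11), n_pairs, 11,
              dimnames = list(sprintf("l%03d", 1:n_pairs), NULL))
  g <- matrix(rnorm(n_pairs * 11), n_pairs, 11,
              dimnames = list(sprintf("g%03d", 1:n_pairs), NULL))
  r <- cross_correlation(list(lipids = l, genes = g))
  for (i in seq_len(n_pairs)) {
    expect_lt(abs(r[i, i] - pearson_bf(l[i, ], g[i, ])), 1e-12)
  }
  expect_true(all(r >= -1 & r <= 1))
  # exact endpoints
  li <- matrix(c(1, 3, 2, 5, 4), 1, dimnames = list("lip", NULL))
  expect_equal(cross_correlation(list(lipids = li, genes = li))[1, 1], 1)
  expect_equal(cross_correlation(list(lipids = li,
                                      genes = -li))[1, 1], -1)
  # constant profiles are NA with a warning
  cst <- matrix(1, 1, 5, dimnames = list("const", NULL))
  expect_warning(rc <- cross_correlation(list(lipids = cst,
                                              genes = li[, 1:5, drop = FALSE])),
                 "constant")
  expect_true(is.na(rc[1, 1]))
})

test_that("biclustering labels P1/P2 by TAG correlation and respects forced cases", {
  r <- cross_correlation(int_prof)
  tags <- rownames(r)[grepl("^TAG", rownames(r))]
  bic <- bicluster_and_label(r, tag_ids = tags)
  ts <- tidy(bic)
  expect_equal(sort(unique(ts$multiomic_cluster)), c("P1", "P2", "P3"))
  agg <- ts |>
    dplyr::group_by(multiomic_cluster) |>
    dplyr::summarise(m = mean(mean_r_tag))
  expect_equal(agg$multiomic_cluster[which.min(agg$m)], "P1")
  expect_equal(agg$multiomic_cluster[which.max(agg$m)], "P2")
  expect_identical(ts$sign, ifelse(ts$mean_r_tag > 0, "positive", "negative"))
  expect_error(bicluster_and_label(r, tag_ids = character()), "tag_ids")
  expect_error(bicluster_and_label(r, tag_ids = "nope"), "absent")
})

test_that("genes constructed to correlate +1 with every TAG are assigned P2", {
  cells <- 11
  rising <- seq_len(cells)
  hump <- c(1, 3, 5, 6, 5, 3, 1, 0.5, 0.2, 0.1, 0)
  l <- rbind(TAG1 = rising, TAG2 = 2 * rising + 1, PC1 = rev(rising),
             PE1 = rev(rising) * 1.5)
  g <- rbind(gpos1 = 3 * rising + 2, gpos2 = rising,
             gneg1 = -rising, gneg2 = 10 - rising, gmid = hump)
  bic <- bicluster_and_label(cross_correlation(list(lipids = l, genes = g)),
                             k_lipids = 2, k_genes = 3,
                             tag_ids = c("TAG1", "TAG2"))
  ts <- tidy(bic)
  expect_equal(ts$mean_r_tag[ts$gene_id == "gpos1"], 1)
  expect_true(all(ts$multiomic_cluster[ts$gene_id %in% c("gpos1", "gpos2")] == "P2"))
  expect_true(all(ts$multiomic_cluster[ts$gene_id %in% c("gneg1", "gneg2")] == "P1"))
  expect_equal(ts$multiomic_cluster[ts$gene_id == "gmid"], "P3")
})

test_that("negating gene profiles negates correlations and swaps P1/P2 and green/red", {
  prof_neg <- int_prof
  prof_neg$genes <- -prof_neg$genes
  r <- cross_correlation(int_prof)
  rn <- cross_correlation(prof_neg)
  expect_equal(rn, -r, tolerance = 1e-12)
  tags <- rownames(r)[grepl("^TAG", rownames(r))]
  b1 <- bicluster_and_label(r, tag_ids = tags)
  b2 <- bicluster_and_label(rn, tag_ids = tags)
  t1 <- tidy(b1); t2 <- tidy(b2)
  expect_equal(t2$mean_r_tag, -t1$mean_r_tag, tolerance = 1e-12)
  swap <- c(P1 = "P2", P2 = "P1", P3 = "P3")
  expect_identical(t2$multiomic_cluster, unname(swap[t1$multiomic_cluster]))
  ann <- make_pathway_annotation(small_transcriptome$truth, seed = 6)
  rx <- dplyr::select(ann, gene_id, reaction_id)
  c1 <- reaction_color_map(t1, rx)
  c2 <- reaction_color_map(t2, rx)
  cswap <- c(green = "red", red = "green", neutral = "neutral")
  expect_identical(c2$color, unname(cswap[c1$color]))
})

test_that("pathway TAG fractions cover only annotated genes and flag majorities", {
  ts <- tibble::tibble(gene_id = sprintf("g%d", 1:6),
                       mean_r_tag = c(0.9, 0.8, -0.5, -0.6, -0.7, 0.2),
                       sign = c("positive", "positive", "negative", "negative",
                                "negative", "positive"),
                       multiomic_cluster = "P3")
  ann <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4", "g5"),
                        pathway = c("synthesis", "synthesis", "ribosome",
                                    "ribosome", "ribosome"))
  pf <- pathway_tag_fractions(ts, ann) # g6 unannotated: excluded
  expect_equal(sum(pf$n_genes), 5)
  expect_equal(pf$frac_pos[pf$pathway == "synthesis"], 1.0)
  expect_equal(pf$frac_neg[pf$pathway == "ribosome"], 1.0)
  expect_true(all(pf$frac_pos + pf$frac_neg == 1))
  expect_identical(pf$majority_positive, pf$frac_pos > 0.5)
  expect_equal(pf$pathway[1], "synthesis") # most TAG-positive on top
})

test_that("cluster overlap forms a consistent contingency with unshared genes reported", {
  rna <- tibble::tibble(item_id = sprintf("g%d", 1:6),
                        cluster_label = c("C1", "C1", "C2", "C2", "C3", "C3"))
  ts <- tibble::tibble(gene_id = sprintf("g%d", 2:7),
                       mean_r_tag = 0.5, sign = "positive",
                       multiomic_cluster = c("P1", "P2", "P2", "P3", "P1", "P1"))
  ov <- cluster_overlap(rna, ts)
  expect_equal(sum(ov$n), 5) # g1 and g7 unshared
  expect_equal(unname(attr(ov, "unshared")), c(1, 1))
  marg <- ov |> dplyr::group_by(rna_cluster) |> dplyr::summarise(n = sum(n))
  expect_equal(marg$n, c(1, 2, 2))
  # identical partitions give a diagonal table
  same <- tibble::tibble(gene_id = rna$item_id, mean_r_tag = 1,
                         sign = "positive",
                         multiomic_cluster = c("P1", "P1", "P2", "P2", "P3", "P3"))
  ov2 <- cluster_overlap(rna, same)
  off <- dplyr::filter(ov2, (rna_cluster == "C1") != (multiomic_cluster == "P1"),
                       n > 0)
  expect_equal(dplyr::n_distinct(dplyr::filter(ov2, n > 0)$rna_cluster), 3)
  expect_equal(sum(ov2$n > 0), 3)
})

test_that("reaction colors resolve conflicts by mean correlation with a neutral band", {
  ts <- tibble::tibble(gene_id = c("a", "b", "c"),
                       mean_r_tag = c(0.6, -0.6, 0.4),
                       sign = c("positive", "negative", "positive"),
                       multiomic_cluster = "P3")
  rx <- tibble::tibble(gene_id = c("a", "b", "c", "zz"),
                       reaction_id = c("R_TIE", "R_TIE", "R_POS", "R_ORPHAN"))
  expect_warning(cm <- reaction_color_map(ts, rx), "R_ORPHAN")
  expect_equal(cm$color[cm$reaction_id == "R_TIE"], "neutral") # mean exactly 0
  expect_equal(cm$color[cm$reaction_id == "R_POS"], "green")
  wide <- reaction_color_map(ts, rx[1:3, ], neutral_eps = 0.5)
  expect_equal(wide$correlation_sign[wide$reaction_id == "R_POS"], "neutral")
})
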