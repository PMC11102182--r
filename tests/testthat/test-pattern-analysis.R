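suppressMessages({
  base_norm <- normalize_counts(small_transcriptome$counts)
  base_scaled <- scale_rows(base_norm)
})

test_that("duplicated sample groups split perfectly at k = 2", {
  set.seed(4)
  block <- matrix(rnorm(200), 20, 10)
  m <- cbind(block + 5, block - 5) # two exact groups
  colnames(m) <- sprintf("smp%02d", 1:20)
  x <- tibble::as_tibble(m, rownames = "gene_id")
  cl <- hcluster_samples(scale_rows(x), k = 2)
  truth <- rep(c("A", "B"), each = 10)
  expect_equal(adjusted_rand(tidy(cl)$cluster_label, truth), 1)
  # k = n gives singletons
  cl_n <- hcluster_samples(scale_rows(x), k = 20)
  expect_equal(dplyr::n_distinct(tidy(cl_n)$cluster_label), 20)
  expect_error(hcluster_samples(scale_rows(x), k = 21), "exceeds")
})

test_that("feature clustering uses correlation distance: affine copies merge, negations split", {
  x <- tibble::tibble(gene_id = c("f", "f_affine", "f_neg"),
                      s1 = c(1, 10, -1), s2 = c(2, 20, -2),
                      s3 = c(3, 30, -3), s4 = c(2.5, 25, -2.5))
  cl <- tidy(hcluster_features(x, k = 2))
  expect_equal(cl$cluster_label[cl$item_id == "f"],
               cl$cluster_label[cl$item_id == "f_affine"])
  expect_false(cl$cluster_label[cl$item_id == "f"] ==
                 cl$cluster_label[cl$item_id == "f_neg"])
  const <- tibble::tibble(gene_id = c("a", "b", "c"), s1 = c(1, 1, 2),
                          s2 = c(2, 1, 3), s3 = c(3, 1, 5))
  expect_error(hcluster_features(const, k = 2), "constant")
})

test_that("feature clustering is invariant to per-feature affine rescaling", {
  set.seed(11)
  scl <- base_scaled
  m <- omic_mat(scl)
  m2 <- m * runif(nrow(m), 0.5, 4) + rnorm(nrow(m)) # row-wise affine
  x2 <- tibble::as_tibble(m2, rownames = "gene_id")
  c1 <- tidy(hcluster_features(scl, 3))
  c2 <- tidy(hcluster_features(x2, 3))
  expect_equal(adjusted_rand(c1$cluster_label, c2$cluster_label), 1)
})

test_that("trend labels anchor C1/C2/C3 to down/flat/up and invert with the effect sign", {
  cl <- hcluster_features(base_scaled, 3) |>
    label_clusters_by_trend(base_norm, default_design)
  lab <- join_truth(tidy(cl), small_transcriptome$truth)
  expect_gte(adjusted_rand(lab$cluster_label, lab$cluster), 0.9)
  by_lab <- dplyr::count(lab, cluster_label, cluster) |>
    dplyr::group_by(cluster_label) |>
    dplyr::slice_max(n, n = 1)
  expect_equal(by_lab$cluster[by_lab$cluster_label == "C1"], "down")
  expect_equal(by_lab$cluster[by_lab$cluster_label == "C3"], "up")
  expect_identical(cl$trend$trend, sort(cl$trend$trend))
})

test_that("pca reproduces rank structure with fixed signs and monotone variance", {
  # rank-1 data: all variance on PC1
  t_axis <- 1:8
  m <- outer(c(1, -2, 3, 0.5), t_axis)
  colnames(m) <- sprintf("s%d", 1:8)
  x <- tibble::as_tibble(m, rownames = "gene_id")
  p <- pca_samples(x, n_components = 2)
  expect_equal(p$variance$variance_fraction[1], 1.0, tolerance = 1e-12)
  p2 <- pca_samples(base_scaled, n_components = 5)
  vf <- p2$variance$variance_fraction
  expect_true(all(diff(vf) <= 1e-12))
  expect_equal(sum(vf), 1) # full-rank sum
  # sign convention: largest-magnitude loading positive
  for (j in 1:5) {
    v <- p2$loadings[[sprintf("PC%d", j)]]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_error(pca_samples(base_scaled, n_components = 100), "exceeds")
})

test_that("pca separates starved from replete samples at 12 h and 36 h", {
  p <- pca_samples(base_scaled, n_components = 2)
  sc <- dplyr::left_join(p$scores, default_design, by = "sample_id") |>
    dplyr::filter(timepoint %in% c(12, 36))
  fit <- suppressWarnings(
    stats::glm(I(nitrogen_state == "starved") ~ PC1 + PC2,
               data = sc, family = stats::binomial))
  pred <- stats::predict(fit, type = "response") > 0.5
  expect_equal(mean(pred == (sc$nitrogen_state == "starved")), 1)
})

test_that("geneset fractions count membership with the bar-chart ranking", {
  ann <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
    pathway = c("all_down", "all_down", "mixed", "mixed", "silent", "silent"))
  de <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       direction = c("down", "down", "up"))
  gf <- geneset_fractions(de, ann)
  expect_equal(gf$frac_down[gf$pathway == "all_down"], 1.0)
  expect_equal(gf$sort_rank[gf$pathway == "all_down"], 3) # bottom
  expect_equal(gf$frac_up[gf$pathway == "mixed"], 0.5)
  expect_equal(gf$frac_up[gf$pathway == "silent"], 0)
  expect_equal(gf$frac_down[gf$pathway == "silent"], 0)
  expect_true(all(gf$frac_up + gf$frac_down <= 1))
  # permutation invariance of input order
  gf2 <- geneset_fractions(de[c(3, 1, 2), ], ann[sample(6), ])
  expect_equal(gf, gf2)
  expect_error(geneset_fractions(de, ann,
                                 universe = tibble::tibble(pathway = "all_down",
                                                           n_genes = 2)),
               "absent from universe")
})
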