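test_that("log-CPM normalization is scale-invariant and monotone", {
  counts <- tibble::tibble(gene_id = c("a", "b", "c"),
                           s1 = c(0L, 100L, 900L),
                           s2 = c(0L, 200L, 1800L)) # s2 = 2x s1 library
  norm <- normalize_counts(counts)
  expect_equal(norm$s1[1], 0) # log2(0 + 1)
  expect_lt(max(abs(norm$s1 - norm$s2)), 1e-9)
  expect_true(all(diff(norm$s1) > 0))
  zero <- tibble::tibble(gene_id = "a", s1 = 0L, s2 = 5L)
  expect_error(normalize_counts(zero), "s1")
  expect_error(normalize_counts(counts, pseudocount = 0), "pseudocount")
})

test_that("row scaling centers, scales by population sd, drops constants, and is idempotent", {
  x <- tibble::tibble(gene_id = c("g1", "g2"),
                      s1 = c(1, 5), s2 = c(2, 5), s3 = c(3, 5))
  expect_message(scl <- scale_rows(x), "dropped")
  expect_equal(attr(scl, "dropped"), "g2")
  # (1,2,3): centered (-1,0,1), population sd = sqrt(2/3)
  expect_equal(unlist(scl[1, -1], use.names = FALSE),
               c(-1, 0, 1) / sqrt(2 / 3))
  twice <- scale_rows(scl)
  expect_equal(as.data.frame(twice), as.data.frame(scl), tolerance = 1e-12,
               ignore_attr = TRUE)
  # every retained row has mean ~0 and population sd ~1
  big <- scale_rows(normalize_counts(small_transcriptome$counts))
  m <- omic_mat(big)
  expect_lt(max(abs(rowMeans(m))), 1e-9)
  expect_lt(max(abs(apply(m, 1, function(v) sqrt(mean((v - mean(v))^2))) - 1)), 1e-9)
})

test_that("fold changes are replicate means in log space with strict direction calls", {
  d <- make_design(cn_ratios = c(5, 100), timepoints = list(`5` = 8, `100` = 8),
                   n_replicates = 2, starvation_onset = c(`5` = 36, `100` = 12))
  norm <- tibble::tibble(gene_id = c("same", "quad"),
                         !!!stats::setNames(
                           list(c(5, 3), c(5, 3), c(5, 5), c(5, 5)),
                           d$sample_id))
  fc <- fold_changes(norm, d, 100, 5, 8)
  expect_equal(fc$log2fc, c(0, 2))
  expect_equal(fc$direction, c("none", "up"))
  # antisymmetry
  rev <- fold_changes(norm, d, 5, 100, 8)
  expect_equal(rev$log2fc, -fc$log2fc)
  expect_equal(rev$direction, c("none", "down"))
  expect_error(fold_changes(norm, d, 100, 5, 36), "36")
})

test_that("the twofold filter uses a strict boundary", {
  fc <- tibble::tibble(gene_id = c("at", "above", "below", "down"),
                       contrast = "x", log2fc = c(1.0, 1.0001, 0.9999, -1.5),
                       direction = NA)
  de <- de_filter(fc, threshold = 2)
  expect_equal(de$gene_id, c("above", "down"))
  expect_equal(de$direction, c("up", "down"))
  expect_error(de_filter(fc, threshold = 1), "threshold")
})

test_that("uniform library inflation changes no fold change or scaled value", {
  counts <- small_transcriptome$counts
  inflated <- counts
  inflated[[2]] <- inflated[[2]] * 3L
  n1 <- normalize_counts(counts); n2 <- normalize_counts(inflated)
  f1 <- fold_changes(n1, default_design, 100, 5, 12)
  f2 <- fold_changes(n2, default_design, 100, 5, 12)
  expect_equal(f1$log2fc, f2$log2fc, tolerance = 1e-9)
  suppressMessages({
    s1 <- scale_rows(n1); s2 <- scale_rows(n2)
  })
  expect_equal(as.data.frame(s1), as.data.frame(s2), tolerance = 1e-9)
})

test_that("planted up genes are called up when the baseline is still replete", {
  sim <- simulate_transcriptome(late_onset_design, n_genes = 1000, seed = 17)
  fc <- fold_changes(normalize_counts(sim$counts), late_onset_design, 100, 5, 36)
  up <- sim$truth$gene_id[sim$truth$cluster == "up"]
  expect_gte(mean(fc$direction[fc$gene_id %in% up] == "up"), 0.95)
})
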