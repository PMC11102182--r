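# Shared fixtures, built in code. Small problem sizes keep the default run
# fast; the acceptance tests use the full study-scale conditions.

default_design <- make_design()

# design in which the C/N 5 baseline stays replete through 36 h (starvation
# onset is configurable; used for contrasts at 36 h)
late_onset_design <- make_design(
  starvation_onset = c(`5` = 88, `100` = 12, `150` = 12))

small_transcriptome <- simulate_transcriptome(default_design, n_genes = 200,
                                              seed = 101)
small_lipidome <- simulate_lipidome(default_design, noise_cv = 0.1, seed = 101)
noisefree_lipidome <- simulate_lipidome(default_design, noise_cv = 0, seed = 101)

omic_mat <- function(x, drop = c("lipid_class", "is_internal_standard")) {
  keep <- setdiff(names(x), c(names(x)[1], drop))
  m <- as.matrix(x[keep])
  rownames(m) <- x[[1]]
  m
}

# independent two-pass Pearson correlation (the oracle for cross_correlation)
pearson_bf <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

join_truth <- function(assignment, truth) {
  dplyr::left_join(assignment, truth, by = c(item_id = "gene_id"))
}
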