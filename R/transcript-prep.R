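#' Log-CPM normalization of a count matrix
#'
#' Library-size normalization to log2 counts per million:
#' `log2(count / column_sum * 1e6 + pseudocount)`. Monotone in the count
#' within a sample and invariant to uniform library-size inflation.
#'
#' @param counts Wide tibble `gene_id` + one non-negative integer column per
#'   sample; column sums must be positive.
#' @param pseudocount Positive offset added before the log (default 1, so a
#'   zero count maps to 0).
#' @return Wide tibble of normalized values, same shape as `counts`.
#' @export
normalize_counts <- function(counts, pseudocount = 1) {
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  m <- omic_matrix(counts, names(counts)[1])
  if (any(m < 0, na.rm = TRUE)) abort("counts must be >= 0")
  lib <- colSums(m)
  if (any(lib <= 0)) {
    abort(paste0("zero column sum in sample(s): ",
                 paste(colnames(m)[lib <= 0], collapse = ", ")))
  }
  norm <- log2(sweep(m, 2, lib, "/") * 1e6 + pseudocount)
  matrix_tibble(norm, names(counts)[1])
}

#' Row-wise centering and scaling
#'
#' The heatmap preprocessing step: each retained row is centered (row mean
#' subtracted) then scaled by its population standard deviation (divide by
#' n), giving rows with mean 0 and sd 1. Rows with sd below `min_sd`
#' (constant genes) carry no profile shape and are dropped; their ids are
#' attached as the `"dropped"` attribute and reported.
#'
#' Idempotent: scaling an already-scaled matrix returns it unchanged.
#'
#' @param x Wide tibble: id column first, then >= 2 sample columns.
#' @param min_sd Minimum population sd for a row to be retained.
#' @return Scaled wide tibble with attribute `dropped` (character ids).
#' @export
scale_rows <- function(x, min_sd = 1e-8) {
  id_col <- names(x)[1]
  m <- omic_matrix(x, id_col)
  if (ncol(m) < 2) abort("row scaling needs at least 2 samples")
  mu <- rowMeans(m)
  sds <- apply(m, 1, pop_sd)
  keep <- sds >= min_sd
  dropped <- rownames(m)[!keep]
  if (length(dropped) > 0) {
    rlang::inform(paste0(length(dropped), " near-constant row(s) dropped"))
  }
  scaled <- (m[keep, , drop = FALSE] - mu[keep]) / sds[keep]
  out <- matrix_tibble(scaled, id_col)
  attr(out, "dropped") <- dropped
  out
}

#' Fold changes between two conditions at a timepoint
#'
#' Computes per-gene log2 fold changes for the contrast `cond_a` vs `cond_b`
#' at one timepoint, as the difference of replicate means of log-normalized
#' values (symmetric in up/down, stable at low counts through the
#' pseudocount). Direction calls use the strict twofold-style rule of
#' [de_filter()]: `up` iff `log2fc > log2(threshold)`, `down` iff
#' `log2fc < -log2(threshold)`, otherwise `none`.
#'
#' Antisymmetric: swapping `cond_a` and `cond_b` negates every `log2fc` and
#' swaps the `up`/`down` labels.
#'
#' @param normalized Normalized wide tibble from [normalize_counts()].
#' @param design Design table covering the samples.
#' @param cond_a,cond_b C/N ratios to contrast (a vs b; b is the baseline).
#' @param timepoint Timepoint (h) at which to contrast.
#' @param threshold Fold-ratio threshold for direction calls (> 1).
#' @return Tibble `gene_id`, `contrast`, `log2fc`, `direction`.
#' @examples
#' sim <- simulate_transcriptome(make_design(), n_genes = 100, seed = 1)
#' fc <- fold_changes(normalize_counts(sim$counts), make_design(),
#'                    cond_a = 100, cond_b = 5, timepoint = 36)
#' head(fc)
#' @export
fold_changes <- function(normalized, design, cond_a, cond_b, timepoint,
                         threshold = 2) {
  check_design(design)
  id_col <- names(normalized)[1]
  m <- omic_matrix(normalized, id_col)
  pick <- function(cond) {
    ids <- design$sample_id[design$condition == cond &
                              design$timepoint == timepoint]
    ids <- intersect(ids, colnames(m))
    if (length(ids) == 0) {
      abort(sprintf("no samples for condition %s at %s h", cond, timepoint))
    }
    ids
  }
  a <- rowMeans(m[, pick(cond_a), drop = FALSE])
  b <- rowMeans(m[, pick(cond_b), drop = FALSE])
  lfc <- a - b
  cut <- log2(threshold)
  tibble::tibble(
    gene_id = rownames(m),
    contrast = sprintf("CN%s_vs_CN%s@%sh", cond_a, cond_b, timepoint),
    log2fc = unname(lfc),
    direction = dplyr::case_when(lfc > cut ~ "up",
                                 lfc < -cut ~ "down",
                                 TRUE ~ "none")
  )
}

#' Twofold differential-expression filter
#'
#' Selects genes whose expression changed by strictly more than
#' `threshold`-fold in either direction: `|log2fc| > log2(threshold)`. A gene
#' sitting exactly at the boundary is excluded ("greater than" is strict).
#' No significance testing is involved — the rule is purely fold-change
#' based.
#'
#' @param fc Fold-change table from [fold_changes()].
#' @param threshold Fold-ratio threshold (> 1), default twofold.
#' @return Tibble `gene_id`, `direction` (`up`/`down`).
#' @export
de_filter <- function(fc, threshold = 2) {
  if (threshold <= 1) abort("threshold must be > 1")
  cut <- log2(threshold)
  fc %>%
    dplyr::filter(abs(.data$log2fc) > cut) %>%
    dplyr::transmute(.data$gene_id,
                     direction = ifelse(.data$log2fc > 0, "up", "down"))
}
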