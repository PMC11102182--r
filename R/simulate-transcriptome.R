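#' Simulate an RNA-seq count matrix with planted response clusters
#'
#' Draws gene-level counts from a negative-binomial model over the samples of
#' a design table, planting three transcript response clusters: `down` genes
#' lose expression under nitrogen starvation, `up` genes gain it, `flat`
#' genes ignore the nitrogen state. Per-gene baseline abundances are
#' log-normal, library sizes vary log-normally around `mean_lib_size`, and
#' starved samples have the mean of `up` genes multiplied (and of `down`
#' genes divided) by `2^effect_log2fc`.
#'
#' With `dispersion = 0` counts are Poisson (the negative-binomial limit),
#' which is the "noise-floor" setting used by the exact recovery checks.
#'
#' Two modeling choices keep the planted structure recoverable from
#' within-sample (CPM-style) normalized data, where only relative abundances
#' survive. First, the default cluster proportions are mass-balanced: at the
#' default fourfold effect, the read mass released by `down` genes
#' (`0.4 * (1 - 1/4)`) matches the mass gained by `up` genes
#' (`0.1 * (4 - 1)`), so starvation does not displace the relative abundance
#' of unaffected genes — and, as observed in nitrogen-starved yeasts, far
#' more genes shut down than are induced. Second, `flat` genes share a
#' nitrogen-independent growth-phase program: a log-normal expression bump
#' peaking in the exponential phase (`phase_amplitude` in log2 units per
#' gene), which leaves every fixed-timepoint contrast at zero but gives the
#' flat cluster the mutual correlation that real co-regulated housekeeping
#' programs show. Set `phase_amplitude = c(0, 0)` for memoryless flat genes.
#'
#' @param design Design table from [make_design()].
#' @param n_genes Number of genes (>= 3).
#' @param cluster_props Length-3 numeric, proportions of `down`/`flat`/`up`
#'   genes; must sum to 1.
#' @param effect_log2fc Planted absolute log2 fold change between starved and
#'   replete states (>= 0).
#' @param dispersion Negative-binomial dispersion shared across genes
#'   (variance = mu + dispersion * mu^2); `0` gives Poisson counts.
#' @param mean_lib_size Expected library size (total counts per sample).
#' @param lib_size_cv Coefficient of variation of the log-normal library-size
#'   draw around `mean_lib_size`; `0` fixes every library size.
#' @param phase_amplitude Length-2 range (log2 units) of the per-gene
#'   amplitude of the growth-phase bump on `flat` genes; drawn uniformly.
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return A list with elements
#'   \describe{
#'     \item{counts}{tibble `gene_id` + one integer column per sample.}
#'     \item{truth}{tibble `gene_id`, `cluster` (`down`/`flat`/`up`) and
#'       `tag_sign` (`negative`/`none`/`positive`), the planted sign of the
#'       gene's correlation with storage-lipid accumulation.}
#'   }
#'
#' @examples
#' sim <- simulate_transcriptome(make_design(), n_genes = 50, seed = 1)
#' dim(sim$counts)
#' dplyr::count(sim$truth, cluster)
#' @export
simulate_transcriptome <- function(design,
                                   n_genes = 2000,
                                   cluster_props = c(down = 0.4, flat = 0.5, up = 0.1),
                                   effect_log2fc = 2,
                                   dispersion = 0.05,
                                   mean_lib_size = 5e6,
                                   lib_size_cv = 0.1,
                                   phase_amplitude = c(0.8, 1.2),
                                   seed = 1) {
  check_design(design)
  if (n_genes < 3) abort("n_genes must be >= 3")
  if (length(cluster_props) != 3 || abs(sum(cluster_props) - 1) > 1e-8) {
    abort("cluster_props must be three proportions summing to 1")
  }
  if (dispersion < 0) abort("dispersion must be >= 0")
  if (effect_log2fc < 0) abort("effect_log2fc must be >= 0")

  n_samples <- nrow(design)
  withr::with_seed(seed, {
    gene_id <- sprintf("g%04d", seq_len(n_genes))
    cluster <- sample(rep(c("down", "flat", "up"),
                          times = round_props(cluster_props, n_genes)))

    # relative abundances: log-normal, heavy-ish tail as in bulk RNA-seq
    abund <- exp(stats::rnorm(n_genes, mean = 0, sd = 1.2))
    abund <- abund / sum(abund)

    lib_size <- mean_lib_size * exp(stats::rnorm(n_samples, 0, lib_size_cv))

    starved <- design$nitrogen_state == "starved"
    shift <- matrix(1, n_genes, n_samples)
    shift[cluster == "up", starved] <- 2^effect_log2fc
    shift[cluster == "down", starved] <- 2^(-effect_log2fc)

    # growth-phase bump on flat genes: Gaussian in log-time around the
    # exponential phase (~14 h), standardized over the design's samples;
    # single-timepoint designs carry no phase variation
    bump <- exp(-(log(design$timepoint / 14))^2 / 0.5)
    bump_sd <- pop_sd(bump)
    bump <- if (bump_sd > 0) (bump - mean(bump)) / bump_sd else rep(0, n_samples)
    flat_idx <- which(cluster == "flat")
    amp <- stats::runif(length(flat_idx), phase_amplitude[1], phase_amplitude[2])
    shift[flat_idx, ] <- 2^(amp %o% bump)

    mu <- (abund %o% lib_size) * shift
    counts <- if (dispersion == 0) {
      stats::rpois(length(mu), lambda = mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    counts <- matrix(counts, n_genes, n_samples,
                     dimnames = list(gene_id, design$sample_id))

    truth <- tibble::tibble(
      gene_id = gene_id,
      cluster = cluster,
      tag_sign = c(down = "negative", flat = "none", up = "positive")[cluster]
    )
    list(counts = matrix_tibble(counts, "gene_id"), truth = truth)
  })
}

# integer cluster sizes that honour the proportions and sum to n
round_props <- function(p, n) {
  sizes <- floor(p * n)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- p * n - sizes
    bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
    sizes[bump] <- sizes[bump] + 1
  }
  sizes
}
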