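#' Default pathway scheme for the annotation generator
#'
#' Pathway classes paired with the planted transcript cluster they draw from,
#' echoing the kinds of processes regulated under nitrogen starvation in
#' oleaginous yeasts: translation/transcription-type machinery shuts down,
#' lipid biosynthetic and carbohydrate pathways come up, housekeeping stays
#' flat.
#'
#' @return Tibble with columns `pathway`, `source_cluster`.
#' @export
default_pathway_scheme <- function() {
  tibble::tribble(
    ~pathway,                          ~source_cluster,
    "translation",                     "down",
    "transcription",                   "down",
    "secondary metabolism",            "down",
    "RNA polymerase",                  "down",
    "aminoacyl-tRNA biosynthesis",     "down",
    "amino acid metabolism",           "down",
    "fatty acid biosynthesis",         "up",
    "fatty acid metabolism",           "up",
    "glycerolipid metabolism",         "up",
    "inositol phosphate metabolism",   "up",
    "complex carbohydrate metabolism", "up",
    "cell cycle",                      "flat",
    "DNA repair",                      "flat"
  )
}

#' Generate a pathway annotation with configurable cluster purity
#'
#' Assigns genes to pathway classes so that each pathway draws a fraction
#' `purity` of its members from one planted transcript cluster (its
#' `source_cluster` in the scheme) and the remainder uniformly from the other
#' clusters. Each gene within a pathway is drawn from the source cluster
#' independently with probability `purity`, so over many seeds the expected
#' source-cluster fraction equals `purity`. Genes may belong to several
#' pathways; pathway members are also grouped into reactions of up to
#' `genes_per_reaction` genes, giving a gene-to-reaction map for
#' pathway-map coloring.
#'
#' @param truth Planted truth from [simulate_transcriptome()] (needs
#'   `gene_id`, `cluster`).
#' @param scheme Tibble `pathway`, `source_cluster` (see
#'   [default_pathway_scheme()]); pathways with no members are dropped.
#' @param genes_per_pathway Members drawn per pathway.
#' @param purity Probability that a member comes from the source cluster.
#' @param genes_per_reaction Reaction granularity within a pathway.
#' @param seed Integer seed.
#' @return Tibble with columns `gene_id`, `pathway`, `reaction_id`.
#' @examples
#' sim <- simulate_transcriptome(make_design(), n_genes = 300, seed = 1)
#' ann <- make_pathway_annotation(sim$truth, purity = 1, seed = 1)
#' head(ann)
#' @export
make_pathway_annotation <- function(truth,
                                    scheme = default_pathway_scheme(),
                                    genes_per_pathway = 20,
                                    purity = 1,
                                    genes_per_reaction = 2,
                                    seed = 1) {
  stopifnot(all(c("gene_id", "cluster") %in% names(truth)))
  if (purity < 0 || purity > 1) abort("purity must be in [0, 1]")
  bad <- setdiff(unique(scheme$source_cluster), unique(truth$cluster))
  if (length(bad) > 0) {
    abort(paste0("scheme references unknown cluster(s): ",
                 paste(bad, collapse = ", ")))
  }

  by_cluster <- split(truth$gene_id, truth$cluster)
  withr::with_seed(seed, {
    purrr::pmap_dfr(scheme, function(pathway, source_cluster) {
      pool_src <- by_cluster[[source_cluster]]
      pool_other <- unlist(by_cluster[setdiff(names(by_cluster), source_cluster)],
                           use.names = FALSE)
      n <- min(genes_per_pathway, length(pool_src) + length(pool_other))
      if (n == 0) return(NULL)
      from_src <- stats::rbinom(n, 1, purity) == 1
      n_src <- min(sum(from_src), length(pool_src))
      n_oth <- min(n - n_src, length(pool_other))
      genes <- c(sample(pool_src, n_src), sample(pool_other, n_oth))
      genes <- sample(genes) # interleave so reactions mix origins
      slug <- toupper(gsub("[^A-Za-z]+", "_", pathway))
      tibble::tibble(
        gene_id = genes,
        pathway = pathway,
        reaction_id = sprintf("R_%s_%02d", slug,
                              ceiling(seq_along(genes) / genes_per_reaction))
      )
    })
  })
}
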