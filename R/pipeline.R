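#' Pipeline run configuration
#'
#' Assembles and validates the full parameter set of an end-to-end run.
#' Every parameter has a documented default (the study-layout defaults of
#' the individual stage functions); unknown blocks or keys are rejected so a
#' typo cannot silently fall back to a default. A config serialized with
#' [write_config()] and re-read with [read_config()] reproduces the run
#' bit-for-bit given the same seed.
#'
#' @param seed Integer master seed for all stochastic stages.
#' @param design Block passed to [make_design()] (`cn_ratios`, `timepoints`,
#'   `n_replicates`, `starvation_onset`).
#' @param transcriptome Block for [simulate_transcriptome()] (`n_genes`,
#'   `cluster_props`, `effect_log2fc`, `dispersion`, `mean_lib_size`).
#' @param lipidome Block for [simulate_lipidome()] (`noise_cv`) and
#'   [remodel_params()] overrides under `remodel`.
#' @param annotation Block for [make_pathway_annotation()]
#'   (`genes_per_pathway`, `purity`).
#' @param transcripts Block for normalization/DE (`pseudocount`, `threshold`,
#'   `contrast` = list(`cond_a`, `cond_b`, `timepoint`)).
#' @param cluster Block for clustering/PCA (`k_features`, `k_samples`,
#'   `linkage`, `n_components`).
#' @param integration Block for the multi-omic stage (`tag_classes`,
#'   `k_lipids`, `k_genes`, `per_replicate`, `neutral_eps`).
#' @return A validated `lipomix_config` list.
#' @examples
#' cfg <- pipeline_config(seed = 7, transcriptome = list(n_genes = 500))
#' cfg$transcriptome$n_genes
#' @export
pipeline_config <- function(seed = 1,
                            design = list(),
                            transcriptome = list(),
                            lipidome = list(),
                            annotation = list(),
                            transcripts = list(),
                            cluster = list(),
                            integration = list()) {
  defaults <- list(
    seed = 1,
    design = list(cn_ratios = c(5, 100, 150),
                  timepoints = list(`5` = c(8, 12, 36),
                                    `100` = c(8, 12, 36, 88),
                                    `150` = c(8, 12, 36, 88)),
                  n_replicates = 3,
                  starvation_onset = c(`5` = 36, `100` = 12, `150` = 12)),
    transcriptome = list(n_genes = 2000,
                         cluster_props = c(down = 0.4, flat = 0.5, up = 0.1),
                         effect_log2fc = 2, dispersion = 0.05,
                         mean_lib_size = 5e6),
    lipidome = list(noise_cv = 0.1, remodel = list()),
    annotation = list(genes_per_pathway = 20, purity = 1,
                      genes_per_reaction = 2),
    # contrast at 12 h: under the default nitrogen map the C/N 5 baseline is
    # still replete there, while at 36 h every condition is starved and the
    # starved-vs-replete contrast is empty by construction
    transcripts = list(pseudocount = 1, threshold = 2,
                       contrast = list(cond_a = 100, cond_b = 5, timepoint = 12)),
    cluster = list(k_features = 3, k_samples = 5, linkage = "complete",
                   n_components = 2),
    integration = list(tag_classes = "TAG", k_lipids = 3, k_genes = 3,
                       per_replicate = FALSE, neutral_eps = 0)
  )
  user <- list(seed = seed, design = design, transcriptome = transcriptome,
               lipidome = lipidome, annotation = annotation,
               transcripts = transcripts, cluster = cluster,
               integration = integration)
  cfg <- defaults
  cfg$seed <- seed
  for (block in setdiff(names(defaults), "seed")) {
    extra <- setdiff(names(user[[block]]), names(defaults[[block]]))
    if (length(extra) > 0) {
      abort(paste0("unknown key(s) in config block '", block, "': ",
                   paste(extra, collapse = ", ")))
    }
    cfg[[block]] <- utils::modifyList(defaults[[block]], as.list(user[[block]]))
  }
  # canonical shapes (YAML round-trips named vectors as lists)
  cfg$design$cn_ratios <- as.numeric(unlist(cfg$design$cn_ratios))
  cfg$design$timepoints <- lapply(cfg$design$timepoints,
                                  function(v) as.numeric(unlist(v)))
  cfg$design$starvation_onset <- unlist(cfg$design$starvation_onset)
  cfg$transcriptome$cluster_props <- unlist(cfg$transcriptome$cluster_props)
  cfg$integration$tag_classes <- as.character(unlist(cfg$integration$tag_classes))
  structure(cfg, class = "lipomix_config")
}

#' Write / read a pipeline config as YAML
#'
#' @param config A `lipomix_config` from [pipeline_config()].
#' @param path YAML path.
#' @return `path` (writer) or the re-validated config (reader).
#' @export
write_config <- function(config, path) {
  # named atomic vectors become named lists so YAML keeps them as maps
  namify <- function(x) {
    if (is.list(x)) lapply(x, namify)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(namify(unclass(config)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  extra <- setdiff(names(raw),
                   c("seed", "design", "transcriptome", "lipidome",
                     "annotation", "transcripts", "cluster", "integration"))
  if (length(extra) > 0) {
    abort(paste0("unknown config block(s): ", paste(extra, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

#' Run the full pipeline
#'
#' Executes all stages in dependency order — simulate, quantify,
#' transcripts, cluster, genesets, integrate, report — writing every stage
#' output as headered TSV (plus Newick dendrograms and the reaction-color
#' JSON) under `out_dir`, and a `manifest.json` recording the config, the
#' package version and an MD5 checksum per output file. Identical configs
#' and seeds give identical outputs and checksums. A stage failure leaves
#' completed outputs in place; the manifest then names the failed stage.
#'
#' @param config A `lipomix_config`; defaults to [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param figures Also save the report figures as PDFs (off by default;
#'   figure files embed timestamps and are excluded from the checksum
#'   manifest either way).
#' @return The run manifest, invisibly: list with `config`, `version`,
#'   `completed`, `failed_stage`, `checksums`.
#' @examples
#' \donttest{
#' man <- run_pipeline(pipeline_config(transcriptome = list(n_genes = 200)),
#'                     out_dir = tempfile())
#' names(man$checksums)
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, figures = FALSE) {
  stopifnot(inherits(config, "lipomix_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- new.env(parent = emptyenv())
  completed <- character()
  failed <- NULL
  out <- function(name) file.path(out_dir, name)

  stages <- list(
    simulate = function() {
      d <- config$design
      res$design <- make_design(d$cn_ratios, d$timepoints, d$n_replicates,
                                d$starvation_onset)
      tc <- config$transcriptome
      res$tr <- simulate_transcriptome(res$design, n_genes = tc$n_genes,
                                       cluster_props = unlist(tc$cluster_props),
                                       effect_log2fc = tc$effect_log2fc,
                                       dispersion = tc$dispersion,
                                       mean_lib_size = tc$mean_lib_size,
                                       seed = config$seed)
      lc <- config$lipidome
      res$lp <- simulate_lipidome(res$design,
                                  remodel = do.call(remodel_params,
                                                    lc$remodel %||% list()),
                                  noise_cv = lc$noise_cv,
                                  seed = config$seed + 1)
      an <- config$annotation
      res$annotation <- make_pathway_annotation(
        res$tr$truth, genes_per_pathway = an$genes_per_pathway,
        purity = an$purity, genes_per_reaction = an$genes_per_reaction,
        seed = config$seed + 2)
      write_omic_tsv(res$design, out("design.tsv"))
      write_omic_tsv(res$tr$counts, out("counts.tsv"))
      write_omic_tsv(res$tr$truth, out("truth_genes.tsv"))
      write_omic_tsv(res$lp$intensities, out("intensities.tsv"))
      write_omic_tsv(res$lp$cocktail, out("cocktail.tsv"))
      write_omic_tsv(res$lp$truth, out("truth_lipids.tsv"))
      write_omic_tsv(res$annotation, out("annotation.tsv"))
    },
    quantify = function() {
      res$quant <- quantify(res$lp$intensities, res$lp$cocktail)
      res$classes <- aggregate_classes(res$quant)
      res$fractions <- pool_fractions(res$classes)
      res$class_summary <- replicate_summary(res$classes, res$design)
      write_omic_tsv(res$quant, out("quant.tsv"))
      write_omic_tsv(res$classes, out("class_amounts.tsv"))
      write_omic_tsv(res$fractions, out("pool_fractions.tsv"))
      write_omic_tsv(res$class_summary, out("class_summary.tsv"))
    },
    transcripts = function() {
      tp <- config$transcripts
      res$normalized <- normalize_counts(res$tr$counts, tp$pseudocount)
      res$scaled <- scale_rows(res$normalized)
      ct <- tp$contrast
      res$fc <- fold_changes(res$normalized, res$design, ct$cond_a, ct$cond_b,
                             ct$timepoint, threshold = tp$threshold)
      res$de <- de_filter(res$fc, tp$threshold)
      write_omic_tsv(res$fc, out("fold_changes.tsv"))
      write_omic_tsv(res$de, out("de_genes.tsv"))
    },
    cluster = function() {
      cl <- config$cluster
      res$gene_clusters <- hcluster_features(res$scaled, cl$k_features,
                                             cl$linkage) %>%
        label_clusters_by_trend(res$normalized, res$design)
      res$sample_clusters <- hcluster_samples(res$scaled, cl$k_samples,
                                              cl$linkage)
      res$pca <- pca_samples(res$scaled, cl$n_components)
      write_omic_tsv(tidy(res$gene_clusters), out("gene_clusters.tsv"))
      write_omic_tsv(tidy(res$sample_clusters), out("sample_clusters.tsv"))
      write_omic_tsv(res$pca$scores, out("pca_scores.tsv"))
      write_omic_tsv(res$pca$variance, out("pca_variance.tsv"))
      write_dendrogram(res$gene_clusters, out("gene_dendrogram.nwk"))
      write_dendrogram(res$sample_clusters, out("sample_dendrogram.nwk"))
    },
    genesets = function() {
      res$geneset <- geneset_fractions(res$de, res$annotation)
      write_omic_tsv(res$geneset, out("geneset_fractions.tsv"))
    },
    integrate = function() {
      ig <- config$integration
      res$profiles <- align_profiles(res$quant, res$normalized, res$design,
                                     per_replicate = ig$per_replicate)
      res$corr <- cross_correlation(res$profiles)
      tag_ids <- res$quant$species_id[res$quant$lipid_class %in% ig$tag_classes]
      res$biclusters <- bicluster_and_label(res$corr, ig$k_lipids, ig$k_genes,
                                            tag_ids = tag_ids)
      res$tag_fractions <- pathway_tag_fractions(res$biclusters$tag_signs,
                                                 res$annotation)
      res$overlap <- cluster_overlap(res$gene_clusters, res$biclusters$tag_signs)
      res$colors <- reaction_color_map(res$biclusters$tag_signs,
                                       res$annotation,
                                       neutral_eps = ig$neutral_eps)
      write_omic_tsv(matrix_tibble(res$corr, "lipid_id"), out("correlation.tsv"))
      write_omic_tsv(res$biclusters$tag_signs, out("tag_signs.tsv"))
      write_omic_tsv(res$tag_fractions, out("pathway_tag_fractions.tsv"))
      write_omic_tsv(res$overlap, out("cluster_overlap.tsv"))
      write_omic_tsv(res$colors, out("reaction_colors.tsv"))
      write_reaction_colors(res$colors, out("reaction_colors.json"))
    },
    report = function() {
      rep <- build_report(res)
      write_omic_tsv(rep$pool_trajectories, out("report_pool_trajectories.tsv"))
      write_omic_tsv(rep$pathway_table, out("report_pathways.tsv"))
      if (figures) {
        for (nm in names(rep$plots)) {
          ggplot2::ggsave(out(paste0("report_", nm, ".pdf")), rep$plots[[nm]],
                          width = 7, height = 5)
        }
      }
      res$report <- rep
    }
  )

  for (nm in names(stages)) {
    ok <- tryCatch({stages[[nm]](); TRUE},
                   error = function(e) {
                     failed <<- list(stage = nm, message = conditionMessage(e))
                     FALSE
                   })
    if (!ok) break
    completed <- c(completed, nm)
  }

  files <- setdiff(list.files(out_dir),
                   c("manifest.json", grep("\\.pdf$", list.files(out_dir), value = TRUE)))
  checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(checksums) <- files
  manifest <- list(
    version = as.character(utils::packageVersion("lipomix")),
    config = unclass(config),
    completed = completed,
    failed_stage = if (is.null(failed)) NULL else failed,
    checksums = checksums
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(failed)) {
    abort(sprintf("stage '%s' failed: %s (completed: %s)", failed$stage,
                  failed$message, paste(completed, collapse = ", ")))
  }
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the summary report from pipeline results
#'
#' Collects the headline tables and figures of a finished run: pool-fraction
#' trajectories (remodeling crossover), the ranked pathway fraction tables,
#' PCA scores and the correlation clustermap.
#'
#' @param results Environment or list of stage results as produced inside
#'   [run_pipeline()] (needs `design`, `fractions`, `geneset`,
#'   `tag_fractions`, `pca`, `corr`, `biclusters`).
#' @return List with `pool_trajectories`, `pathway_table` and `plots`
#'   (named list of ggplot objects).
#' @export
build_report <- function(results) {
  r <- as.list(results)
  needed <- c("design", "fractions", "geneset", "tag_fractions", "pca",
              "corr", "biclusters")
  missing_in <- setdiff(needed, names(r))
  if (length(missing_in) > 0) {
    abort(paste0("report inputs missing: ", paste(missing_in, collapse = ", ")))
  }
  pool <- r$fractions %>%
    dplyr::left_join(dplyr::select(r$design, "sample_id", "condition",
                                   "timepoint"), by = "sample_id") %>%
    dplyr::group_by(.data$condition, .data$timepoint) %>%
    dplyr::summarise(frac_phospholipid = mean(.data$frac_phospholipid),
                     frac_storage = mean(.data$frac_storage),
                     frac_other = mean(.data$frac_other),
                     .groups = "drop")
  list(
    pool_trajectories = pool,
    pathway_table = r$geneset,
    plots = list(
      pool_fractions = plot_pool_fractions(r$fractions, r$design),
      genesets = plot_pathway_fractions(r$geneset),
      tag_pathways = plot_pathway_fractions(r$tag_fractions),
      pca = autoplot(r$pca, design = r$design),
      clustermap = plot_correlation_map(r$corr, r$biclusters)
    )
  )
}
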