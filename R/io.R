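# Readers and writers. All tables are headered TSV (wide: feature rows,
# sample columns); dendrograms go to Newick; reaction colors and run
# manifests to JSON.

#' Read a wide omic table from TSV
#'
#' @param path TSV path; first column is the feature id, remaining columns
#'   samples (plus optional annotation columns such as `lipid_class`).
#' @return Tibble.
#' @export
read_omic_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a wide omic table (or any tibble) to TSV
#'
#' @param x Tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_omic_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a lipid intensity table
#'
#' Wide TSV with columns `species_id`, `lipid_class`, `is_internal_standard`
#' then per-sample intensities. Validates the schema and that every class
#' has an internal-standard row.
#'
#' @param path TSV path.
#' @return Tibble as consumed by [quantify()].
#' @export
read_intensity_tsv <- function(path) {
  x <- read_omic_tsv(path)
  needed <- c("species_id", "lipid_class", "is_internal_standard")
  missing_col <- setdiff(needed, names(x))
  if (length(missing_col) > 0) {
    abort(paste0(path, ": missing column(s) ", paste(missing_col, collapse = ", ")))
  }
  x$is_internal_standard <- as.logical(x$is_internal_standard)
  no_std <- setdiff(unique(x$lipid_class[!x$is_internal_standard]),
                    unique(x$lipid_class[x$is_internal_standard]))
  if (length(no_std) > 0) {
    abort(paste0(path, ": no internal-standard row for class(es) ",
                 paste(no_std, collapse = ", ")))
  }
  x
}

#' Read a sample design table
#'
#' @param path TSV with the [make_design()] schema.
#' @return Design tibble.
#' @export
read_design_tsv <- function(path) {
  check_design(read_omic_tsv(path))
}

#' Read an internal-standard cocktail table
#'
#' @param path TSV with columns `lipid_class`, `standard_species_id`,
#'   `spiked_amount`.
#' @return Cocktail tibble.
#' @export
read_cocktail_tsv <- function(path) {
  x <- read_omic_tsv(path)
  needed <- c("lipid_class", "standard_species_id", "spiked_amount")
  missing_col <- setdiff(needed, names(x))
  if (length(missing_col) > 0) {
    abort(paste0(path, ": missing column(s) ", paste(missing_col, collapse = ", ")))
  }
  if (any(x$spiked_amount <= 0)) abort(paste0(path, ": spiked amounts must be > 0"))
  x
}

#' Serialize a dendrogram to Newick
#'
#' @param clusters A `lipomix_clusters` object (or a bare `hclust`).
#' @param path Output `.nwk` path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(clusters, path) {
  hc <- if (inherits(clusters, "lipomix_clusters")) clusters$hclust else clusters
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Export a reaction color map as flat JSON
#'
#' Writes `{"reaction_id": "#hex", ...}` consumable by pathway-map
#' renderers: green (`#178a3b`) for TAG-positive reactions, red (`#c0392b`)
#' for TAG-negative, grey (`#9e9e9e`) for neutral.
#'
#' @param color_map Tibble from [reaction_color_map()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_reaction_colors <- function(color_map, path) {
  hex <- c(green = "#178a3b", red = "#c0392b", neutral = "#9e9e9e")
  flat <- as.list(stats::setNames(unname(hex[color_map$color]),
                                  color_map$reaction_id))
  jsonlite::write_json(flat, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
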