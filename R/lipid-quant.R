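#' One-point internal-standard quantification of lipid intensities
#'
#' Converts peak intensities to absolute amounts by one-point calibration:
#' each species' intensity is divided by the intensity of its class's spiked
#' internal standard in the same sample and multiplied by the standard's mole
#' amount, then divided by the sample's OD600 units:
#' `amount = intensity / IS_intensity * spiked_amount / od_units`,
#' in pmol per OD600 unit.
#'
#' Samples where a class standard has zero or missing intensity are flagged
#' with a warning and that class's amounts are set missing (`NA`), never
#' zero — a zero intensity is a measurement, an unusable standard is not.
#'
#' @param intensities Wide tibble: `species_id`, `lipid_class`,
#'   `is_internal_standard`, then one intensity column per sample. Standards
#'   are matched by `standard_species_id` from the cocktail.
#' @param cocktail Tibble `lipid_class`, `standard_species_id`,
#'   `spiked_amount` (pmol), one row per class.
#' @param od_units Scalar or per-sample named vector of OD600 units extracted
#'   (> 0). Defaults to 1, i.e. intensities already per-OD.
#' @return Quant table: `species_id`, `lipid_class` + one amount column per
#'   sample (pmol/OD600); internal-standard rows excluded.
#' @examples
#' sim <- simulate_lipidome(make_design(), noise_cv = 0, seed = 1)
#' quant <- quantify(sim$intensities, sim$cocktail)
#' quant[1:3, 1:4]
#' @export
quantify <- function(intensities, cocktail, od_units = 1) {
  needed <- c("species_id", "lipid_class", "is_internal_standard")
  missing_col <- setdiff(needed, names(intensities))
  if (length(missing_col) > 0) {
    abort(paste0("intensity table missing column(s): ",
                 paste(missing_col, collapse = ", ")))
  }
  analytes <- dplyr::filter(intensities, !.data$is_internal_standard)
  standards <- dplyr::filter(intensities, .data$is_internal_standard)
  samples <- sample_cols(intensities, "species_id",
                         c("lipid_class", "is_internal_standard"))
  if (length(samples) == 0) abort("intensity table has no sample columns")

  classes <- unique(analytes$lipid_class)
  no_std <- setdiff(classes, cocktail$lipid_class)
  std_rows <- cocktail[match(classes, cocktail$lipid_class), ]
  absent <- std_rows$standard_species_id[!is.na(std_rows$lipid_class) &
                                           !std_rows$standard_species_id %in% standards$species_id]
  if (length(no_std) > 0 || length(absent) > 0) {
    bad_classes <- union(no_std, std_rows$lipid_class[std_rows$standard_species_id %in% absent])
    affected <- analytes$species_id[analytes$lipid_class %in% bad_classes]
    abort(paste0("no usable internal standard for class(es) ",
                 paste(bad_classes, collapse = ", "),
                 "; affected species: ", paste(affected, collapse = ", ")))
  }

  if (length(od_units) == 1 && is.null(names(od_units))) {
    od <- stats::setNames(rep(od_units, length(samples)), samples)
  } else {
    miss <- setdiff(samples, names(od_units))
    if (length(miss) > 0) {
      abort(paste0("od_units missing for sample(s): ", paste(miss, collapse = ", ")))
    }
    od <- od_units[samples]
  }
  if (any(od <= 0)) abort("od_units must all be > 0")

  a_mat <- omic_matrix(analytes, "species_id",
                       c("lipid_class", "is_internal_standard"))[, samples, drop = FALSE]
  s_mat <- omic_matrix(standards, "species_id",
                       c("lipid_class", "is_internal_standard"))[, samples, drop = FALSE]
  if (any(a_mat < 0, na.rm = TRUE)) abort("intensities must be >= 0")

  std_of_class <- stats::setNames(cocktail$standard_species_id, cocktail$lipid_class)
  spike_of_class <- stats::setNames(cocktail$spiked_amount, cocktail$lipid_class)
  is_int <- s_mat[std_of_class[analytes$lipid_class], , drop = FALSE]

  bad <- !is.finite(is_int) | is_int <= 0
  if (any(bad)) {
    flagged <- unique(colnames(is_int)[colSums(bad) > 0])
    warn(paste0("zero/missing standard intensity; amounts set missing in sample(s): ",
                paste(flagged, collapse = ", ")))
    is_int[bad] <- NA_real_
  }

  amounts <- a_mat / is_int * spike_of_class[analytes$lipid_class]
  amounts <- sweep(amounts, 2, od, "/")

  matrix_tibble(amounts, "species_id") %>%
    dplyr::mutate(lipid_class = analytes$lipid_class, .after = "species_id")
}

#' Aggregate species amounts to lipid-class totals
#'
#' Sums member species within each lipid class, per sample. Missing species
#' amounts propagate to the class total (`NA`), preserving the rule that
#' absence is not zero. The grand total over classes equals the grand total
#' over species.
#'
#' @param quant Quant table from [quantify()] (or any wide tibble with
#'   `species_id`, `lipid_class` + sample columns).
#' @return Wide tibble `lipid_class` + one amount column per sample.
#' @export
aggregate_classes <- function(quant) {
  if (!"lipid_class" %in% names(quant)) abort("quant table needs a lipid_class column")
  samples <- sample_cols(quant, "species_id", "lipid_class")
  quant %>%
    dplyr::group_by(.data$lipid_class) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(samples), sum), .groups = "drop")
}

#' Phospholipid / storage-lipid pool fractions per sample
#'
#' The lipid-remodeling statistic: per sample, the fraction of the total
#' quantified lipid pool held in membrane phospholipids and in storage
#' lipids, plus the remainder (`frac_other`). The three fractions sum to 1
#' and are invariant to rescaling a sample's total. Samples with zero (or
#' missing) total are flagged with a warning and get `NA` fractions.
#'
#' @param class_amounts Class-by-sample table from [aggregate_classes()].
#' @param phospholipid_classes,storage_classes Disjoint class sets; defaults
#'   are the quantified membrane classes PC/PE/PG/PI and the storage classes
#'   DAG/TAG.
#' @return Tibble `sample_id`, `frac_phospholipid`, `frac_storage`,
#'   `frac_other`, `total` (pmol/OD600).
#' @examples
#' sim <- simulate_lipidome(make_design(), noise_cv = 0, seed = 1)
#' cls <- aggregate_classes(quantify(sim$intensities, sim$cocktail))
#' pool_fractions(cls)
#' @export
pool_fractions <- function(class_amounts,
                           phospholipid_classes = c("PC", "PE", "PG", "PI"),
                           storage_classes = c("DAG", "TAG")) {
  if (length(intersect(phospholipid_classes, storage_classes)) > 0) {
    abort("phospholipid and storage class sets must be disjoint")
  }
  m <- omic_matrix(class_amounts, "lipid_class")
  total <- colSums(m)
  phos <- colSums(m[rownames(m) %in% phospholipid_classes, , drop = FALSE])
  stor <- colSums(m[rownames(m) %in% storage_classes, , drop = FALSE])
  degenerate <- !is.finite(total) | total <= 0
  if (any(degenerate)) {
    warn(paste0("zero or missing lipid total; fractions undefined for: ",
                paste(colnames(m)[degenerate], collapse = ", ")))
    total[degenerate] <- NA_real_
  }
  tibble::tibble(
    sample_id = colnames(m),
    frac_phospholipid = unname(phos / total),
    frac_storage = unname(stor / total),
    frac_other = unname(1 - phos / total - stor / total),
    total = unname(total)
  )
}

#' Replicate means and standard deviations per condition and timepoint
#'
#' Collapses biological replicates of any wide omic table (species, class or
#' gene rows) to per-cell (condition x timepoint) means and standard
#' deviations, e.g. for trajectory plots with error bars. Cells with a
#' single replicate get `sd = 0`.
#'
#' @param x Wide tibble: one id column (first) + sample columns.
#' @param design Design table; every sample column must appear in it.
#' @return Long tibble `feature_id`, `condition`, `timepoint`, `n`, `mean`, `sd`.
#' @export
replicate_summary <- function(x, design) {
  check_design(design)
  id_col <- names(x)[1]
  drop <- intersect(c("lipid_class", "is_internal_standard"), names(x))
  samples <- sample_cols(x, id_col, drop)
  unknown <- setdiff(samples, design$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("sample(s) absent from design: ", paste(unknown, collapse = ", ")))
  }
  x %>%
    dplyr::select(dplyr::all_of(c(id_col, samples))) %>%
    tidyr::pivot_longer(-dplyr::all_of(id_col),
                        names_to = "sample_id", values_to = "value") %>%
    dplyr::rename(feature_id = dplyr::all_of(id_col)) %>%
    dplyr::left_join(dplyr::select(design, "sample_id", "condition", "timepoint"),
                     by = "sample_id") %>%
    dplyr::group_by(.data$feature_id, .data$condition, .data$timepoint) %>%
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$value),
                     sd = ifelse(dplyr::n() > 1, stats::sd(.data$value), 0),
                     .groups = "drop")
}
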