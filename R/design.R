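#' Build a sample design table for a carbon-to-nitrogen time course
#'
#' Lays out the full factorial sampling plan of a nitrogen-limitation growth
#' experiment: cultures grown at several molar carbon-to-nitrogen (C/N)
#' ratios, sampled at fixed timepoints with biological replicates. High C/N
#' media run out of nitrogen early while growth continues; low C/N media stay
#' nitrogen replete until the carbon supply is exhausted, at which point the
#' cells experience a late, carbon-driven nitrogen starvation. The per-sample
#' `nitrogen_state` is derived deterministically from the per-condition
#' starvation onset time.
#'
#' The defaults reproduce the study layout used throughout the package:
#' C/N 5, 100 and 150; timepoints 8, 12 and 36 h, with an additional 88 h
#' sample for the two lipid-accumulating conditions (C/N 100 and 150); three
#' biological replicates; starvation onset at 12 h for C/N 100/150 and 36 h
#' for C/N 5.
#'
#' @param cn_ratios Numeric vector of C/N ratios (dimensionless).
#' @param timepoints Named list mapping each C/N ratio (as character) to its
#'   sampling timepoints in hours.
#' @param n_replicates Number of biological replicates per condition and
#'   timepoint (>= 1).
#' @param starvation_onset Named numeric vector mapping each C/N ratio to the
#'   time (h) from which its samples are nitrogen starved; a sample is
#'   `starved` iff `timepoint >= starvation_onset[condition]`.
#'
#' @return A tibble with one row per (condition, timepoint, replicate):
#'   columns `sample_id`, `condition`, `timepoint`, `replicate`,
#'   `nitrogen_state` (`"replete"`/`"starved"`) and `phase_label` (one of
#'   `early_exponential`, `exponential`, `glucose_starvation`,
#'   `nitrogen_starvation`, `oleaginous`).
#'
#' @examples
#' design <- make_design()
#' nrow(design) # 33
#' dplyr::count(design, condition, nitrogen_state)
#' @export
make_design <- function(cn_ratios = c(5, 100, 150),
                        timepoints = list(`5` = c(8, 12, 36),
                                          `100` = c(8, 12, 36, 88),
                                          `150` = c(8, 12, 36, 88)),
                        n_replicates = 3,
                        starvation_onset = c(`5` = 36, `100` = 12, `150` = 12)) {
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  keys <- as.character(cn_ratios)
  unknown <- setdiff(names(timepoints), keys)
  if (length(unknown) > 0) {
    abort(paste0("timepoints given for unknown condition(s): ",
                 paste(unknown, collapse = ", ")))
  }
  missing_tp <- keys[!keys %in% names(timepoints)]
  if (length(missing_tp) > 0) {
    abort(paste0("no timepoints configured for condition(s): ",
                 paste(missing_tp, collapse = ", ")))
  }
  if (any(lengths(timepoints[keys]) == 0)) {
    abort("every condition needs at least one timepoint")
  }
  missing_on <- keys[!keys %in% names(starvation_onset)]
  if (length(missing_on) > 0) {
    abort(paste0("no starvation onset configured for condition(s): ",
                 paste(missing_on, collapse = ", ")))
  }

  design <- purrr::map_dfr(keys, function(k) {
    tidyr::expand_grid(condition = as.numeric(k),
                       timepoint = sort(unique(timepoints[[k]])),
                       replicate = seq_len(n_replicates))
  }) %>%
    dplyr::mutate(
      sample_id = format_sample_id(.data$condition, .data$timepoint, .data$replicate),
      onset = unname(starvation_onset[as.character(.data$condition)]),
      nitrogen_state = ifelse(.data$timepoint >= .data$onset, "starved", "replete"),
      phase_label = phase_of(.data$condition, .data$timepoint, .data$nitrogen_state,
                             min(cn_ratios))
    ) %>%
    dplyr::select("sample_id", "condition", "timepoint", "replicate",
                  "nitrogen_state", "phase_label")
  design
}

# Deterministic growth-phase label from condition/timepoint/nitrogen state.
# The lowest C/N medium is carbon-poor, so its late starvation is driven by
# glucose exhaustion; high C/N media starve for nitrogen while glucose remains.
phase_of <- function(condition, timepoint, nitrogen_state, lowest_cn) {
  dplyr::case_when(
    timepoint <= 8 ~ "early_exponential",
    nitrogen_state == "replete" ~ "exponential",
    timepoint >= 88 ~ "oleaginous",
    condition == lowest_cn ~ "glucose_starvation",
    TRUE ~ "nitrogen_starvation"
  )
}
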