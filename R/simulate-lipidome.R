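#' Default lipid-species catalog
#'
#' Six lipid classes — four membrane glycerophospholipids (PC, PE, PG, PI)
#' and two storage lipids (DAG, TAG) — with five species each, named by a
#' plausible total acyl carbon:double-bond composition.
#'
#' @param n_species Species per class.
#' @return Tibble with columns `species_id`, `lipid_class`.
#' @examples
#' default_lipid_catalog()
#' @export
default_lipid_catalog <- function(n_species = 5) {
  classes <- c("PC", "PE", "PG", "PI", "DAG", "TAG")
  chains <- c("32:1", "34:1", "34:2", "36:2", "36:3", "38:4", "40:5")
  purrr::map_dfr(classes, function(cl) {
    tibble::tibble(
      species_id = sprintf("%s(%s)", cl, chains[seq_len(n_species)]),
      lipid_class = cl
    )
  })
}

#' Default internal-standard cocktail
#'
#' One spiked standard per lipid class with its mole amount in pmol. The
#' amounts are synthetic round numbers on the scale typical for spiked
#' odd-chain standards; real analyses supply their own cocktail table.
#'
#' @param catalog Lipid catalog; classes needing a standard are taken from it.
#' @return Tibble with columns `lipid_class`, `standard_species_id`,
#'   `spiked_amount` (pmol).
#' @examples
#' default_standard_cocktail()
#' @export
default_standard_cocktail <- function(catalog = default_lipid_catalog()) {
  classes <- unique(catalog$lipid_class)
  amounts <- c(PC = 160, PE = 140, PG = 100, PI = 120, DAG = 130, TAG = 120)
  spiked <- ifelse(classes %in% names(amounts), amounts[classes], 100)
  tibble::tibble(
    lipid_class = classes,
    standard_species_id = sprintf("IS_%s", classes),
    spiked_amount = unname(spiked)
  )
}

#' Lipid-remodeling trajectory parameters
#'
#' Parameters of the planted class trajectories used by
#' [simulate_lipidome()]. Each condition carries a remodel clock
#' `clock = max(0, t - onset)` (onset = that condition's nitrogen-starvation
#' onset from the design) and a Hill response
#' `s = clock^hill / (clock^hill + lag^hill)`, exactly zero before onset, so
#' lipid divergence between conditions is structurally delayed relative to
#' the transcript response at onset. Class amounts (pmol per OD600 unit):
#' phospholipids `base * (1 + growth * t) * (1 - loss * s)` (grow with
#' culture age, then are remodeled away); storage lipids
#' `base * (1 + growth * t) + gain * s` (slow age accumulation plus the
#' starvation-driven surge). Optionally TAG dips at the final timepoint of
#' one condition, emulating late TAG catabolism after glucose exhaustion.
#'
#' @param lag Hours from starvation onset to half-maximal remodeling.
#' @param hill Hill exponent of the remodel response.
#' @param phospho_base,storage_base Baseline class amounts (pmol/OD600).
#' @param phospho_growth,storage_growth Linear growth of class amounts with
#'   culture age (fraction of base per hour).
#' @param phospho_loss Fraction of the phospholipid pool remodeled away at
#'   full response (in `[0, 1]`).
#' @param storage_gain Amount (pmol/OD600) added to each storage class at
#'   full response.
#' @param tag_dip_condition C/N ratio whose final timepoint shows a TAG
#'   decline (`NA` to disable).
#' @param tag_dip_factor Multiplier applied to TAG at that timepoint.
#' @return Named list of parameters.
#' @export
remodel_params <- function(lag = 24, hill = 2,
                           phospho_base = 100, storage_base = 20,
                           phospho_growth = 0.03, storage_growth = 0.45,
                           phospho_loss = 0.95, storage_gain = 400,
                           tag_dip_condition = 100, tag_dip_factor = 0.75) {
  stopifnot(lag > 0, hill > 0, phospho_base > 0, storage_base > 0,
            phospho_loss >= 0, phospho_loss <= 1, storage_gain >= 0)
  list(lag = lag, hill = hill,
       phospho_base = phospho_base, storage_base = storage_base,
       phospho_growth = phospho_growth, storage_growth = storage_growth,
       phospho_loss = phospho_loss, storage_gain = storage_gain,
       tag_dip_condition = tag_dip_condition, tag_dip_factor = tag_dip_factor)
}

#' Simulate a lipidomic peak-intensity table with planted remodeling
#'
#' Generates species-level true amounts (pmol per OD600 unit) following the
#' class trajectories of [remodel_params()] — phospholipids rise with culture
#' age then decline after the per-condition starvation onset plus a lag,
#' DAG/TAG rise sigmoidally after onset — and converts them to observed peak
#' intensities through a per-class response factor and multiplicative
#' log-normal noise with coefficient of variation `noise_cv`. One
#' internal-standard row per class is emitted per the cocktail, subject to
#' the same noise model, so [quantify()] on the output inverts the
#' calibration. With `noise_cv = 0` the round trip is exact.
#'
#' @param design Design table from [make_design()]. The per-condition
#'   starvation onset is recovered from its `nitrogen_state` column.
#' @param catalog Tibble `species_id`, `lipid_class` (every species classed).
#' @param cocktail Internal-standard table, one standard per class
#'   (see [default_standard_cocktail()]).
#' @param remodel Trajectory parameters from [remodel_params()].
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   measurement noise (>= 0).
#' @param seed Integer seed.
#'
#' @return A list with elements
#'   \describe{
#'     \item{intensities}{tibble `species_id`, `lipid_class`,
#'       `is_internal_standard`, then one intensity column per sample.}
#'     \item{cocktail}{the cocktail used.}
#'     \item{truth}{tibble of true amounts, `species_id`, `lipid_class` +
#'       sample columns (pmol/OD600).}
#'   }
#' @examples
#' sim <- simulate_lipidome(make_design(), noise_cv = 0, seed = 1)
#' head(sim$truth[, 1:4])
#' @export
simulate_lipidome <- function(design,
                              catalog = default_lipid_catalog(),
                              cocktail = default_standard_cocktail(catalog),
                              remodel = remodel_params(),
                              noise_cv = 0.1,
                              seed = 1) {
  check_design(design)
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  if (anyNA(catalog$lipid_class)) abort("every species needs a lipid class")
  missing_std <- setdiff(unique(catalog$lipid_class), cocktail$lipid_class)
  if (length(missing_std) > 0) {
    abort(paste0("no internal standard for class(es): ",
                 paste(missing_std, collapse = ", ")))
  }
  if (anyDuplicated(cocktail$lipid_class)) {
    abort("cocktail must hold exactly one standard per class")
  }
  if (any(cocktail$spiked_amount <= 0)) abort("spiked amounts must be > 0")

  starved_rows <- dplyr::filter(design, .data$nitrogen_state == "starved")
  onset <- if (nrow(starved_rows) > 0) {
    starved_rows %>%
      dplyr::group_by(.data$condition) %>%
      dplyr::summarise(onset = min(.data$timepoint), .groups = "drop")
  } else {
    tibble::tibble(condition = numeric(), onset = numeric())
  }
  design <- dplyr::left_join(design, onset, by = "condition")
  # a condition never starved within the sampled window: clock stays 0
  design$onset[is.na(design$onset)] <- Inf

  phospho <- c("PC", "PE", "PG", "PI")
  classes <- unique(catalog$lipid_class)
  rf <- stats::setNames(150 * (1 + 0.4 * (seq_along(classes) - 1)), classes)

  final_tp <- design %>%
    dplyr::group_by(.data$condition) %>%
    dplyr::summarise(final = max(.data$timepoint), .groups = "drop")
  design <- dplyr::left_join(design, final_tp, by = "condition")

  class_amount <- function(cl, cond, t, onset_t, final_t) {
    clock <- pmax(0, t - onset_t)
    s <- clock^remodel$hill / (clock^remodel$hill + remodel$lag^remodel$hill)
    s[clock == 0] <- 0
    a <- if (cl %in% phospho) {
      remodel$phospho_base * (1 + remodel$phospho_growth * t) *
        (1 - remodel$phospho_loss * s)
    } else {
      remodel$storage_base * (1 + remodel$storage_growth * t) +
        remodel$storage_gain * s
    }
    if (cl == "TAG" && !is.na(remodel$tag_dip_condition)) {
      dip <- cond == remodel$tag_dip_condition & t == final_t
      a[dip] <- a[dip] * remodel$tag_dip_factor
    }
    a
  }

  # species share of its class total: fixed weights by catalog order
  catalog <- catalog %>%
    dplyr::group_by(.data$lipid_class) %>%
    dplyr::mutate(weight = dplyr::row_number() / sum(dplyr::row_number())) %>%
    dplyr::ungroup()

  truth_mat <- matrix(0, nrow(catalog), nrow(design),
                      dimnames = list(catalog$species_id, design$sample_id))
  for (i in seq_len(nrow(catalog))) {
    truth_mat[i, ] <- catalog$weight[i] *
      class_amount(catalog$lipid_class[i], design$condition,
                   design$timepoint, design$onset, design$final)
  }

  withr::with_seed(seed, {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- function(n) {
      if (noise_cv == 0) rep(1, n) else exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
    }
    obs <- truth_mat * rf[catalog$lipid_class] *
      matrix(noise(length(truth_mat)), nrow(truth_mat))

    is_mat <- matrix(0, nrow(cocktail), nrow(design),
                     dimnames = list(cocktail$standard_species_id, design$sample_id))
    for (i in seq_len(nrow(cocktail))) {
      is_mat[i, ] <- cocktail$spiked_amount[i] * rf[cocktail$lipid_class[i]] *
        noise(nrow(design))
    }

    intensities <- dplyr::bind_rows(
      matrix_tibble(obs, "species_id") %>%
        dplyr::mutate(lipid_class = catalog$lipid_class,
                      is_internal_standard = FALSE, .after = "species_id"),
      matrix_tibble(is_mat, "species_id") %>%
        dplyr::mutate(lipid_class = cocktail$lipid_class,
                      is_internal_standard = TRUE, .after = "species_id")
    )

    truth <- matrix_tibble(truth_mat, "species_id") %>%
      dplyr::mutate(lipid_class = catalog$lipid_class, .after = "species_id")

    list(intensities = intensities, cocktail = cocktail, truth = truth)
  })
}
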