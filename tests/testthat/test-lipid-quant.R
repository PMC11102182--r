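make_toy_intensities <- function() {
  tibble::tibble(
    species_id = c("TAG(50:1)", "TAG(52:2)", "PC(34:1)", "IS_TAG", "IS_PC"),
    lipid_class = c("TAG", "TAG", "PC", "TAG", "PC"),
    is_internal_standard = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    s1 = c(1000, 500, 0, 1000, 2000),
    s2 = c(3000, 1500, 400, 1500, 800)
  )
}
toy_cocktail <- tibble::tibble(
  lipid_class = c("TAG", "PC"),
  standard_species_id = c("IS_TAG", "IS_PC"),
  spiked_amount = c(120, 160)
)

test_that("one-point calibration follows the internal-standard ratio rule", {
  q <- quantify(make_toy_intensities(), toy_cocktail)
  expect_equal(q$s1[q$species_id == "TAG(50:1)"], 1000 / 1000 * 120) # ratio 1
  expect_equal(q$s1[q$species_id == "PC(34:1)"], 0)                  # zero stays zero
  expect_equal(q$s2[q$species_id == "TAG(52:2)"], 1500 / 1500 * 120)
  expect_equal(q$s2[q$species_id == "PC(34:1)"], 400 / 800 * 160)
  expect_false("IS_TAG" %in% q$species_id)
  # od normalization divides through
  q2 <- quantify(make_toy_intensities(), toy_cocktail, od_units = c(s1 = 2, s2 = 4))
  expect_equal(q2$s1, q$s1 / 2)
  expect_equal(q2$s2, q$s2 / 4)
})

test_that("calibration is linear in analyte and inverse in standard intensity", {
  x <- make_toy_intensities()
  q <- quantify(x, toy_cocktail)
  x_scaled <- x
  x_scaled$s1[!x_scaled$is_internal_standard] <- x$s1[!x$is_internal_standard] * 3
  expect_equal(quantify(x_scaled, toy_cocktail)$s1, q$s1 * 3)
  x_std <- x
  x_std$s1[x_std$is_internal_standard] <- x$s1[x$is_internal_standard] * 3
  expect_equal(quantify(x_std, toy_cocktail)$s1, q$s1 / 3)
})

test_that("missing or dead standards are flagged, not imputed", {
  x <- make_toy_intensities()
  expect_error(quantify(x, toy_cocktail[1, ]), "PC")
  x$s1[x$species_id == "IS_TAG"] <- 0
  expect_warning(q <- quantify(x, toy_cocktail), "s1")
  expect_true(all(is.na(q$s1[q$lipid_class == "TAG"])))
  expect_false(anyNA(q$s2))
})

test_that("class aggregation preserves totals and propagates NA", {
  sim <- small_lipidome
  q <- quantify(sim$intensities, sim$cocktail)
  cls <- aggregate_classes(q)
  expect_equal(colSums(omic_mat(cls, drop = NULL)),
               colSums(omic_mat(q)))
  two <- tibble::tibble(species_id = c("a", "b"), lipid_class = "TAG",
                        s1 = c(10, 15), s2 = c(NA, 1))
  agg <- aggregate_classes(two)
  expect_equal(agg$s1, 25)
  expect_true(is.na(agg$s2))
})

test_that("pool fractions are exact on hand-computable input and scale-invariant", {
  cls <- tibble::tibble(lipid_class = c("PC", "PE", "TAG", "DAG"),
                        s1 = c(30, 10, 50, 10))
  pf <- pool_fractions(cls)
  expect_equal(pf$frac_phospholipid, 0.40)
  expect_equal(pf$frac_storage, 0.60)
  expect_equal(pf$frac_other, 0)
  # all-storage sample
  only_tag <- tibble::tibble(lipid_class = "TAG", s1 = 7)
  expect_equal(pool_fractions(only_tag)$frac_storage, 1.0)
  # invariance to per-sample rescaling
  cls_k <- dplyr::mutate(cls, s1 = s1 * 17.3)
  expect_equal(pool_fractions(cls_k)[1:4], pf[1:4])
  # fractions always sum to one
  sim_cls <- aggregate_classes(quantify(small_lipidome$intensities,
                                        small_lipidome$cocktail))
  pf2 <- pool_fractions(sim_cls)
  expect_true(all(abs(pf2$frac_phospholipid + pf2$frac_storage + pf2$frac_other - 1) < 1e-9))
  expect_true(all(pf2$frac_phospholipid >= 0 & pf2$frac_phospholipid <= 1))
})

test_that("degenerate and misconfigured pools are rejected or flagged", {
  expect_error(pool_fractions(tibble::tibble(lipid_class = "PC", s1 = 1),
                              phospholipid_classes = "PC",
                              storage_classes = c("PC", "TAG")),
               "disjoint")
  zero <- tibble::tibble(lipid_class = c("PC", "TAG"), s1 = c(0, 0))
  expect_warning(pf <- pool_fractions(zero), "undefined")
  expect_true(is.na(pf$frac_storage))
})

test_that("replicate summaries collapse cells correctly", {
  x <- tibble::tibble(feature = "f1",
                      !!!stats::setNames(as.list(c(10, 12, 14)),
                                         default_design$sample_id[1:3]))
  rs <- replicate_summary(x, default_design)
  expect_equal(rs$mean, 12)
  expect_equal(rs$sd, sd(c(10, 12, 14)))
  d1 <- make_design(cn_ratios = 5, timepoints = list(`5` = 8),
                    n_replicates = 1, starvation_onset = c(`5` = 36))
  x1 <- tibble::tibble(feature = "f1",
                       !!!stats::setNames(list(5), d1$sample_id))
  expect_equal(replicate_summary(x1, d1)$sd, 0)
  bad <- dplyr::rename(x, zz = 2)
  expect_error(replicate_summary(bad, default_design), "absent from design")
})

test_that("replicate-level quantification noise stays near the planted CV", {
  cvs <- vapply(1:50, function(s) {
    sim <- simulate_lipidome(default_design, noise_cv = 0.1, seed = s)
    q <- quantify(sim$intensities, sim$cocktail)
    rs <- replicate_summary(q, default_design)
    stats::median(rs$sd / rs$mean)
  }, numeric(1))
  # species-level observed CV folds in analyte and standard noise
  expect_true(all(cvs > 0 & cvs < 0.3))
})
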