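spectrum_row <- function(id, sequence, modifications, ratio, ef = NA_real_,
                         condition = "BCR/ABL", conf = 95) {
  tibble::tibble(spectrum_id = id, protein = "PROT1", sequence = sequence,
                 modifications = modifications, id_confidence = conf,
                 error_factor = ef, condition = condition, ratio = ratio)
}

test_that("identification-confidence filter is strictly greater-than", {
  spectra <- tibble::tibble(id_confidence = c(10, 20, 21, 95))
  expect_equal(filter_by_id_confidence(spectra)$id_confidence, c(21, 95))
  expect_equal(nrow(filter_by_id_confidence(spectra[0, ])), 0)
  expect_equal(nrow(filter_by_id_confidence(spectra, threshold = 0)), 4)
  marked <- mark_used_spectra(spectra)
  expect_identical(marked$used, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("spectra collapse to distinct sequence/modification-set entities", {
  same <- dplyr::bind_rows(
    spectrum_row("s1", "AKSPTLR", "Pho(S3)", 2.0),
    spectrum_row("s2", "AKSPTLR", "Pho(S3)", 2.0))
  ent <- collapse_entities(same)
  expect_equal(nrow(ent), 1)
  expect_equal(ent$ratio, 2.0)
  expect_equal(ent$n_spectra_used, 2)

  # phospho at position 3 vs position 5 of the same sequence: two entities
  posdiff <- dplyr::bind_rows(
    spectrum_row("s1", "AKSPTLR", "Pho(S3)", 2.0),
    spectrum_row("s2", "AKSPTLR", "Pho(T5)", 2.0))
  expect_equal(nrow(collapse_entities(posdiff)), 2)
})

test_that("entity ratios are inverse-squared-log-error-factor weighted", {
  pair <- dplyr::bind_rows(
    spectrum_row("s1", "AKSPTLR", "Pho(S3)", 2.0, ef = 1.1),
    spectrum_row("s2", "AKSPTLR", "Pho(S3)", 8.0, ef = 10))
  # oracle: direct weighted mean with the stated weights
  w <- 1 / log10(c(1.1, 10))^2
  oracle <- exp(sum(w * log(c(2, 8))) / sum(w))
  ent <- collapse_entities(pair)
  expect_equal(ent$ratio, oracle)
  expect_lt(abs(ent$ratio - 2), 0.05)  # dominated by the precise spectrum

  # equal error factors reduce to the unweighted log-mean exactly
  eq <- dplyr::bind_rows(
    spectrum_row("s1", "AKSPTLR", "Pho(S3)", 2.0, ef = 1.5),
    spectrum_row("s2", "AKSPTLR", "Pho(S3)", 8.0, ef = 1.5))
  expect_equal(collapse_entities(eq)$ratio, exp(mean(log(c(2, 8)))))

  # any absent EF in the group: equal weights
  mixed <- dplyr::bind_rows(
    spectrum_row("s1", "AKSPTLR", "Pho(S3)", 2.0, ef = 1.1),
    spectrum_row("s2", "AKSPTLR", "Pho(S3)", 8.0))
  expect_equal(collapse_entities(mixed)$ratio, exp(mean(log(c(2, 8)))))
})

test_that("collapsing is idempotent and conserves spectrum counts", {
  ps <- generate_phospho_study(study_config(n_features = 40,
                                            spectra_per_feature = 3, seed = 9))
  used <- filter_by_id_confidence(ps$spectra)
  ent <- collapse_entities(used)
  expect_lte(nrow(ent), nrow(used))
  # per experiment and condition, entity spectrum counts sum to used spectra
  for (cond in c("BCR/ABL", "internal")) {
    sub_e <- ent[ent$experiment == "exp1" & ent$condition == cond, ]
    sub_u <- used[used$experiment == "exp1" & used$condition == cond, ]
    expect_equal(sum(sub_e$n_spectra_used), nrow(sub_u))
  }
  # collapsing the collapsed table again changes nothing
  again <- collapse_entities(ent[, c("experiment", "protein", "sequence",
                                     "modifications", "condition", "ratio")])
  reord <- ent[order(ent$experiment, ent$protein, ent$sequence,
                     ent$modifications, ent$condition), ]
  expect_equal(again$ratio, reord$ratio)
  expect_equal(nrow(again), nrow(ent))
})

test_that("entity p-values are reported but never drive phospho calls", {
  ps <- generate_phospho_study(study_config(n_features = 40,
                                            spectra_per_feature = 3,
                                            spike_fraction = 0.2,
                                            spike_fold_range = c(3, 3),
                                            seed = 10))
  res <- phospho_pipeline(ps$spectra)
  expect_true(any(!is.na(res$entities$pvalue)))
  # calls exist even where the p-value is absent or large: the interval
  # alone decides
  calls <- res$calls$experiment_calls
  called <- calls[calls$direction != "none", ]
  expect_gt(nrow(called), 0)
  expect_true(any(is.na(called$pvalue) | called$pvalue > 0.05))
})

test_that("stoichiometry compares phospho and protein folds", {
  nfil3 <- stoichiometry_ratio(1.98, 2.07)
  expect_equal(nfil3$stoichiometry, 1.98 / 2.07)
  expect_identical(nfil3$classification, "unchanged")

  changed <- stoichiometry_ratio(2.0, 1.0)
  expect_equal(changed$stoichiometry, 2)
  expect_identical(changed$classification, "changed")

  for (x in c(0.2, 1, 5)) {
    expect_equal(stoichiometry_ratio(x, x)$stoichiometry, 1)
  }
  expect_error(stoichiometry_ratio(-1, 2), "> 0")
})
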