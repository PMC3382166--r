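test_that("single-experiment rule: interval in both modes, p-value only for proteins", {
  null <- deterministic_null(200, sd = 0.1)
  iv <- fit_significance_interval(null, experiment = "exp1")
  expect_lt(iv$upper, 1.4)

  up <- call_single_experiment(list(ratio = 1.8, pvalue = 0.01), iv, null)
  expect_identical(up$direction, "up")
  expect_gte(up$confidence, 0.95)

  # outside the interval but p too large: no protein-mode call
  not_sig <- call_single_experiment(list(ratio = 1.8, pvalue = 0.20), iv, null)
  expect_identical(not_sig$direction, "none")

  # absent p blocks a protein call but not a phospho call
  expect_identical(
    call_single_experiment(list(ratio = 1.8), iv, null)$direction, "none")
  expect_identical(
    call_single_experiment(list(ratio = 1.8), iv, null,
                           mode = "phospho")$direction, "up")

  down <- call_single_experiment(list(ratio = 0.6, pvalue = 0.001), iv, null)
  expect_identical(down$direction, "down")
  expect_lte(down$confidence, -0.95)

  expect_error(
    call_single_experiment(list(ratio = 1.8, experiment = "exp2"), iv, null),
    "exp2")
  tab <- tibble::tibble(feature = "f", condition = "c", ratio = 1.8,
                        experiment = "exp9")
  expect_error(call_experiment(tab, iv, null), "exp9")
})

test_that("ratio and confidence averaging follow the stated conventions", {
  expect_equal(average_ratio(c(2, 2, 2)), 2)
  expect_equal(average_ratio(c(0.5, 2.0)), 1.0)
  set.seed(5)
  x <- exp(rnorm(100))
  expect_equal(average_ratio(x), prod(x)^(1 / length(x)))
  expect_error(average_ratio(numeric()), "no ratios")
  expect_error(average_ratio(c(1, -2)), "> 0")

  expect_equal(average_confidence(c(0.97, 0.97, 0.97)), 0.97)
  expect_equal(average_confidence(c(0.96, -0.96)), 0)
  expect_equal(average_confidence(c(0.99, -0.96, 0.06)), 0.03)
  expect_error(average_confidence(numeric()), "no confidences")
})

make_calls <- function(ratio, direction, confidence = 0.97 * sign(log(ratio))) {
  tibble::tibble(
    feature = "f1", condition = "BCR/ABL",
    experiment = paste0("exp", seq_along(ratio)),
    ratio = ratio, confidence = confidence, direction = direction)
}

test_that("consensus requires a strict majority of quantified experiments", {
  # called in 2 experiments, no ratio recorded in the third
  two_of_two <- make_calls(c(1.8, 1.7, NA), c("up", "up", "none"))
  rec <- consensus_call(two_of_two)
  expect_identical(rec$call, "up")
  expect_equal(rec$n_quantified, 2)

  # quantified but uncalled in the third: 2 of 3 is still a majority
  two_of_three <- make_calls(c(1.8, 1.7, 1.2), c("up", "up", "none"))
  expect_identical(consensus_call(two_of_three)$call, "up")

  # 1 of 3 is not a majority, but suffices under rule = "any"
  one_of_three <- make_calls(c(1.8, 1.1, 1.0), c("up", "none", "none"))
  expect_identical(consensus_call(one_of_three)$call, "none")
  expect_identical(consensus_call(one_of_three, rule = "any")$call, "up")

  # a single quantified experiment is callable (1 of 1)
  singleton <- make_calls(1.9, "up")
  rec1 <- consensus_call(singleton)
  expect_identical(rec1$call, "up")
  expect_equal(rec1$n_quantified, 1)

  # averaged ratio is the geometric mean over quantified experiments
  expect_equal(consensus_call(two_of_three)$avg_ratio,
               exp(mean(log(c(1.8, 1.7, 1.2)))))
  expect_error(consensus_call(two_of_three[0, ]), "empty")
})

test_that("an internal-replicate call in any experiment vetoes the record", {
  calls <- make_calls(c(1.8, 1.7, 1.2), c("up", "up", "none"))
  internal <- tibble::tibble(direction = c("none", "up", "none"))
  rec <- consensus_call(calls, internal)
  expect_identical(rec$call, "none")
  expect_true(rec$internal_flagged)
})

test_that("mixed directions: the majority wins but the conflict is flagged", {
  mixed <- make_calls(c(1.8, 1.7, 0.5), c("up", "up", "down"),
                      confidence = c(0.97, 0.96, -0.98))
  rec <- consensus_call(mixed)
  expect_identical(rec$call, "up")
  expect_true(rec$direction_conflict)
  expect_equal(rec$n_called, 3)
})

test_that("grouped consensus agrees with the single-record operation", {
  study <- tiny_study(spike_fraction = 0.2)
  res <- call_study(study)
  calls <- res$experiment_calls
  onc <- calls[!is_internal_condition(calls$condition), ]
  internal <- calls[is_internal_condition(calls$condition), ]
  picks <- unique(onc[, c("feature", "condition")])
  set.seed(2)
  picks <- picks[sample.int(nrow(picks), 25), ]
  for (i in seq_len(nrow(picks))) {
    sub <- onc[onc$feature == picks$feature[i] &
                 onc$condition == picks$condition[i], ]
    sub_int <- internal[internal$feature == picks$feature[i], ]
    single <- consensus_call(sub, sub_int)
    grouped <- res$consensus[res$consensus$feature == picks$feature[i] &
                               res$consensus$condition == picks$condition[i], ]
    expect_equal(single$call, grouped$call)
    expect_equal(single$avg_ratio, grouped$avg_ratio)
    expect_equal(single$avg_confidence, grouped$avg_confidence)
    expect_equal(single$internal_flagged, grouped$internal_flagged)
  }
})

test_that("null studies stay mostly uncalled; consensus is stricter than one run", {
  study <- generate_study(study_config(n_features = 3600, spike_fraction = 0,
                                       seed = 2))
  res <- call_study(study)
  onc <- res$experiment_calls[
    !is_internal_condition(res$experiment_calls$condition), ]
  single_rate <- mean(onc$direction != "none")
  consensus_rate <- mean(res$consensus$call != "none")
  expect_lte(single_rate, 0.05)
  expect_lt(consensus_rate, single_rate)
})

test_that("spiked studies are recovered in direction, never inverted", {
  study <- generate_study(study_config(
    n_features = 2000, spike_fraction = 0.1, spike_fold_range = c(2, 2),
    log2_null_sd = 0.15, seed = 8))
  res <- call_study(study)
  truth <- study$truth
  truth$true_dir <- ifelse(truth$fold > 1, "up", "down")
  j <- dplyr::inner_join(truth, res$consensus, by = c("feature", "condition"))
  # no spiked pair is ever called in the wrong direction
  expect_equal(sum(j$call != "none" & j$call != j$true_dir), 0)
  # among features surviving the internal-replicate veto, the correct
  # direction is recovered in at least 90% of pairs
  surviving <- j[!j$internal_flagged, ]
  expect_gte(mean(surviving$call == surviving$true_dir), 0.9)
  # direction/ratio coherence over every record
  expect_equal(sum(res$consensus$call == "up" & res$consensus$avg_ratio < 1), 0)
  expect_equal(sum(res$consensus$call == "down" & res$consensus$avg_ratio > 1), 0)
})
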