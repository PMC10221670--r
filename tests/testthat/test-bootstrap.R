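test_that("B = 1 gives singleton CIs equal to the single out-of-bag attribution", {
  d <- simulate_trial(small_params(n = 60, seed = 51))
  md <- model_definition("induction")
  res <- bootstrap_attributions(md, d, cheap_hp(), B = 1, seed = 1)
  s <- res$summary[res$summary$n_oob == 1, ]
  expect_gt(nrow(s), 0)
  expect_equal(s$lower, s$mean, tolerance = 1e-12)
  expect_equal(s$upper, s$mean, tolerance = 1e-12)
  # never-out-of-bag patients are flagged, not dropped
  expect_setequal(unique(res$summary$patient_id), res$patient_id)
  expect_true(all(res$summary$n_oob[is.na(res$summary$mean)] == 0))
})

test_that("per-iteration out-of-bag fraction matches 1 - (1 - 1/N)^N", {
  d <- simulate_trial(small_params(n = 80, seed = 53))
  md <- model_definition("induction")
  B <- 60
  res <- bootstrap_attributions(md, d, cheap_hp(), B = B, seed = 2)
  frac <- tapply(res$draws$patient_id, res$draws$iter,
                 function(x) length(x) / 80)
  expected <- (1 - 1 / 80)^80  # P(patient absent from a draw) ~ e^-1
  expect_lt(abs(mean(frac) - expected), 3 * sd(frac) / sqrt(B))
})

test_that("attributed patients are disjoint from each iteration's training draw", {
  d <- simulate_trial(small_params(n = 50, seed = 55))
  md <- model_definition("induction")
  res <- bootstrap_attributions(md, d, cheap_hp(), B = 10, seed = 3)
  for (b in seq_len(res$B)) {
    oob_ids <- res$draws$patient_id[res$draws$iter == b]
    expect_length(intersect(oob_ids, res$train_rows[[b]]), 0)
    expect_setequal(oob_ids, setdiff(res$patient_id, res$train_rows[[b]]))
  }
  expect_true(all(res$summary$lower <= res$summary$upper, na.rm = TRUE))
})

test_that("split resampling attributes exactly the complement of the train split", {
  d <- simulate_trial(small_params(n = 10, seed = 57))
  md <- model_definition("induction")
  res <- split_attributions(md, d, cheap_hp(), train_frac = 0.5, B = 2,
                            seed = 4)
  expect_equal(res$strategy, "split_without_replacement")
  for (b in 1:2) {
    expect_length(res$train_rows[[b]], 5)
    oob_ids <- res$draws$patient_id[res$draws$iter == b]
    expect_setequal(oob_ids, setdiff(res$patient_id, res$train_rows[[b]]))
  }
})

test_that("resampling input errors are raised", {
  d <- simulate_trial(small_params(n = 40, seed = 59))
  md <- model_definition("induction")
  expect_error(bootstrap_attributions(md, d, cheap_hp(), B = 0), "B must be")
  expect_error(split_attributions(md, d, cheap_hp(), train_frac = 1, B = 2),
               "strictly between 0 and 1")
  expect_error(split_attributions(md, d, cheap_hp(), train_frac = 0, B = 2),
               "strictly between 0 and 1")
})

test_that("dependence bins partition the cohort with a separate placebo bin for exposures", {
  d <- simulate_trial(small_params(n = 220, seed = 61))
  md <- model_definition("induction")
  res <- bootstrap_attributions(md, d, cheap_hp(), B = 8, seed = 5)

  bd_t <- bin_dependence(res, d, "t_I", n_bins = 10)
  expect_equal(nrow(bd_t), 11)  # placebo + 10 quantile bins
  expect_equal(sum(bd_t$n), 220)
  expect_true(bd_t$placebo[1])
  expect_equal(bd_t$median_value[1], 0)
  expect_true(all(diff(bd_t$median_value[-1]) >= 0))
  members <- attr(bd_t, "members")
  expect_setequal(unlist(members), res$patient_id)
  expect_equal(sum(duplicated(unlist(members))), 0)

  bd_c <- bin_dependence(res, d, "c_I", n_bins = 10)
  expect_equal(nrow(bd_c), 10)  # no placebo bin for a confounder
  expect_true(all(diff(bd_c$median_value) >= 0))
  expect_true(all(bd_c$lower <= bd_c$upper))

  expect_error(bin_dependence(res, d, "h_M"), "not part of")
})

test_that("constant attributions give equal bin means and zero-width CIs", {
  ids <- 1:40
  v <- seq(0.1, 4, length.out = 40)
  draws <- do.call(rbind, lapply(1:6, function(b) {
    data.frame(iter = b, patient_id = ids, phi_0 = 0, f = 1.5)
  }))
  res <- structure(list(
    summary = data.frame(patient_id = ids, feature = "f", mean = 1.5,
                         lower = 1.5, upper = 1.5, n_oob = 6L),
    draws = draws, train_rows = replicate(6, integer(0), simplify = FALSE),
    B = 6L, strategy = "with_replacement", train_frac = NA, seed = 1,
    features = "f", model = "toy", patient_id = ids),
    class = "bootstrap_result")
  fake <- data.frame(patient_id = ids, f = v)
  bd <- bin_dependence(res, fake, "f", n_bins = 5)
  expect_equal(bd$mean_attr, rep(1.5, 5))
  expect_equal(bd$upper - bd$lower, rep(0, 5))

  truth <- data.frame(patient_id = ids, f = 1.5)
  ag <- ground_truth_agreement(bd, truth)
  expect_true(all(ag$covered))
  expect_equal(attr(ag, "n_covered"), 5)

  expect_error(ground_truth_agreement(bd, truth[1:10, ]),
               "does not cover")
  expect_error(ground_truth_agreement(bd, data.frame(patient_id = ids, g = 1)),
               "no column")
})
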