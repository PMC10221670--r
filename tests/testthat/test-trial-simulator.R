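test_that("identical params and seed give bit-identical datasets and serializations", {
  p <- small_params(n = 250, seed = 9)
  d1 <- simulate_trial(p)
  d2 <- simulate_trial(p)
  expect_identical(as.data.frame(d1), as.data.frame(d2))

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(d1), f1, row.names = FALSE, na = "")
  write.csv(as.data.frame(d2), f2, row.names = FALSE, na = "")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("placebo patients have zero exposure and maintenance records exist exactly for the active induction arm", {
  d <- simulate_trial(small_params(n = 400, seed = 3))
  expect_true(all(d$t_I[d$r_I == 0] == 0))
  maint_cols <- c("x_M1", "x_M2", "x_M3", "c_M", "r_M", "t_M", "h_F",
                  "p2_true", "y_2")
  for (col in maint_cols) {
    expect_true(all(is.na(d[[col]][d$r_I == 0])), info = col)
    expect_true(all(!is.na(d[[col]][d$r_I == 1])), info = col)
  }
  expect_true(all(d$t_M[d$r_I == 1][d$r_M[d$r_I == 1] == 0] == 0))
  expect_true(all(d$p1_true > 0 & d$p1_true < 1))
  expect_true(all(d$y_1 %in% 0:1))
  expect_true(all(d$y_2[d$r_I == 1] %in% 0:1))
})

test_that("null-effect generator reduces to Bernoulli(sigma(intercept))", {
  d0 <- simulate_trial(null_params(2000, seed = 5, intercept = 0))
  expect_equal(unique(d0$p1_true), 0.5)

  n <- 50000
  d <- simulate_trial(null_params(n, seed = 7, intercept = 0.5))
  target <- plogis(0.5)
  expect_equal(unique(d$p1_true), target)
  tol <- 3 * sqrt(target * (1 - target) / n)
  expect_lt(abs(mean(d$y_1) - target), tol)
})

test_that("latent health decomposes exactly into the stored per-variable contributions", {
  d <- simulate_trial(small_params(n = 500, seed = 11))
  ints <- attr(d, "intercepts")
  expect_equal(d$h_M, d$h_I + d$gt_t_I + d$gt_c_I + ints[["induction"]],
               tolerance = 1e-12)
  m <- d$r_I == 1
  expect_equal(d$h_F[m],
               d$h_M[m] + d$gt_t_M[m] + d$gt_c_M[m] + ints[["maintenance"]],
               tolerance = 1e-12)
  # outcome probabilities never involve the nuisance x covariates
  expect_equal(d$p1_true, plogis(d$h_M), tolerance = 1e-15)
})

test_that("intercept calibration hits the target response rates in expectation", {
  d <- simulate_trial(small_params(n = 5000, seed = 13))
  expect_equal(mean(d$p1_true), 0.402, tolerance = 1e-6)
  expect_equal(mean(d$p2_true[d$r_I == 1]), 0.782, tolerance = 1e-6)
})

test_that("ground-truth effects are mean-subtracted to zero on every pathway and zero for nuisance covariates", {
  d <- simulate_trial(small_params(n = 400, seed = 21))
  for (pw in c("induction", "maintenance_only", "maintenance_from_induction")) {
    eff <- ground_truth_effects(d, pw)
    for (col in setdiff(names(eff), "patient_id")) {
      expect_lt(abs(mean(eff[[col]])), 1e-10)
    }
    xcols <- grep("^x_", names(eff), value = TRUE)
    # exactly zero before subtraction => zero variance after
    for (col in xcols) expect_identical(var(eff[[col]]), 0)
  }
  expect_error(ground_truth_effects(d, "no_such_pathway"))
})

test_that("linear-logit generator yields the closed-form beta * (v - mean(v)) effects", {
  d <- simulate_trial(linear_params(n = 600, seed = 17, beta_c = 0.8,
                                    beta_t = 0.5))
  eff <- ground_truth_effects(d, "induction")
  expect_equal(eff$c_I, 0.8 * (d$c_I - mean(d$c_I)), tolerance = 1e-12)
  expect_equal(eff$t_I, 0.5 * (d$t_I - mean(d$t_I)), tolerance = 1e-12)
})

test_that("default confounder effect is inverted-U: tails lie below the mode", {
  d <- simulate_trial(small_params(n = 2000, seed = 19))
  eff <- ground_truth_effects(d, "induction")
  mode_c <- 0.25
  near <- abs(d$c_I - mode_c) < 0.25
  far <- abs(d$c_I - mode_c) > 1.5
  expect_gt(min(eff$c_I[near]), max(eff$c_I[far]))
})

test_that("true-probability AUROC matches exhaustive pair counting on toys", {
  toy <- data.frame(p1_true = c(0.9, 0.8, 0.2, 0.1), y_1 = c(1, 1, 0, 0),
                    r_I = 0)
  expect_equal(true_probability_auroc(toy, stage = 1), 1.0)
  const <- data.frame(p1_true = rep(0.5, 6), y_1 = c(1, 0, 1, 0, 1, 0),
                      r_I = 0)
  expect_equal(true_probability_auroc(const, stage = 1), 0.5)
  onecls <- data.frame(p1_true = c(0.2, 0.9), y_1 = c(1, 1), r_I = 0)
  expect_error(true_probability_auroc(onecls, stage = 1), "single class")
})

test_that("cohort summary counts the maintenance cohort by the active-arm rule", {
  d <- simulate_trial(small_params(n = 350, seed = 23))
  cs <- summarize_cohort(d)
  expect_equal(cs$n_total, 350)
  expect_equal(cs$n_maintenance, sum(d$r_I == 1))
  expect_equal(cs$induction_response_rate, mean(d$y_1))
  expect_true(cs$n_maintenance <= cs$n_total)

  d0 <- simulate_trial(small_params(n = 50, seed = 2,
                                    randomization_prob_induction = 0))
  cs0 <- summarize_cohort(d0)
  expect_equal(cs0$n_maintenance, 0)
  expect_true(is.na(cs0$maintenance_response_rate))
})

test_that("invalid parameters are rejected", {
  expect_error(trial_params(n_patients = 1), ">= 2")
  bad <- matrix(c(1, 2, 2, 1), 2)  # not PSD, wrong dim too
  expect_error(trial_params(covariate_covariance_spec =
                              list(induction = bad, maintenance = NULL)))
  notpsd <- diag(4); notpsd[1, 2] <- notpsd[2, 1] <- 2
  expect_error(trial_params(covariate_covariance_spec =
                              list(induction = notpsd, maintenance = NULL)),
               "positive semi-definite")
  expect_error(trial_params(randomization_prob_induction = 1.2), "\\[0, 1\\]")
})
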