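test_that("emitted attributions satisfy exact local accuracy and match the learner margin", {
  d <- simulate_trial(small_params(n = 300, seed = 31))
  md <- model_definition("induction")
  for (run in list(in_sample_predict_attribute(md, d, cheap_hp(), seed = 1),
                   cross_val_predict_attribute(md, d, cheap_hp(),
                                               k_folds = 5, seed = 1))) {
    recomposed <- run$attributions$phi_0 + rowSums(phi_matrix(run, md))
    expect_lt(max(abs(recomposed - run$predictions$f_hat)), 1e-6)
    expect_equal(run$predictions$p_hat, plogis(run$predictions$f_hat),
                 tolerance = 1e-12)
  }
  # independent check against the booster's own margin output (float32)
  dsn <- extract_design(d, md)
  model <- fit_classifier(dsn$features, dsn$labels, cheap_hp(), seed = 1)
  att <- attribute(model, dsn$features)
  expect_lt(max(abs(att$f_hat - predict_margin(model, dsn$features))), 1e-4)
})

test_that("cross-validation folds partition the cohort with no training leakage", {
  d <- simulate_trial(small_params(n = 240, seed = 33))
  md <- model_definition("maintenance_only")
  run <- cross_val_predict_attribute(md, d, cheap_hp(), k_folds = 6, seed = 2)
  ids <- extract_design(d, md)$patient_id
  expect_setequal(run$predictions$patient_id, ids)
  expect_equal(nrow(run$predictions), length(ids))  # exactly one row each
  expect_equal(sort(unique(run$predictions$fold)), 1:6)
  expect_identical(run$predictions$scope, rep("out_of_sample", length(ids)))
  # each fold's test patients are exactly those not in its training set
  for (f in 1:6) {
    test_ids <- run$predictions$patient_id[run$predictions$fold == f]
    train_ids <- setdiff(ids, test_ids)
    expect_length(intersect(test_ids, train_ids), 0)
  }
})

test_that("leave-one-out is the k = n limit: singleton folds, no leakage", {
  d <- simulate_trial(small_params(n = 20, seed = 35))
  md <- model_definition("induction")
  run <- cross_val_predict_attribute(md, d, cheap_hp(), k_folds = 20, seed = 3)
  expect_equal(sort(run$predictions$fold), 1:20)
  expect_equal(length(unique(run$predictions$fold)), 20)
})

test_that("a perfectly separating feature yields in-sample AUROC 1 on an 8-row toy", {
  X <- cbind(sep = c(0, 0, 0, 0, 1, 1, 1, 1),
             noise = c(0.1, 0.9, 0.4, 0.7, 0.2, 0.8, 0.5, 0.3))
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  m <- fit_classifier(X, y, cheap_hp(), seed = 4)
  expect_equal(auroc(predict_prob(m, X), y), 1.0)
})

test_that("constant features produce a flat prediction at the base rate", {
  X <- cbind(a = rep(1, 40), b = rep(2, 40))
  y <- rep(c(0, 1, 1, 1), 10)
  m <- fit_classifier(X, y, list(max_depth = 3, eta = 0.3, nrounds = 100),
                      seed = 5)
  p <- predict_prob(m, X)
  expect_equal(max(p) - min(p), 0)
  expect_equal(unique(p), 0.75, tolerance = 0.01)
})

test_that("single-class training labels raise a training error", {
  X <- cbind(a = rnorm(10))
  expect_error(fit_classifier(X, rep(1, 10), cheap_hp()), "single class")
  expect_error(fit_classifier(X[1, , drop = FALSE], 1, cheap_hp()),
               "at least 2 rows")
})

test_that("single-stump attributions match brute-force Shapley coalition enumeration", {
  set.seed(61)
  n <- 80
  X <- cbind(f1 = rnorm(n), f2 = rnorm(n))
  y <- as.numeric(X[, 1] + 0.3 * rnorm(n) > 0)
  hp <- list(max_depth = 1, eta = 1, nrounds = 1, lambda = 0,
             min_child_weight = 0)
  m <- fit_classifier(X, y, hp, seed = 6)

  margin <- function(M) predict_margin(m, M)
  # coalition value: expectation of the margin with off-coalition features
  # drawn from the empirical (training) background
  vfun <- function(x, S) {
    M <- X
    for (j in S) M[, j] <- x[j]
    mean(margin(M))
  }
  att <- attribute(m, X)
  for (i in c(1, 7, 25)) {
    x <- X[i, ]
    v0 <- vfun(x, integer(0)); v1 <- vfun(x, 1); v2 <- vfun(x, 2)
    v12 <- vfun(x, 1:2)
    phi1 <- 0.5 * ((v1 - v0) + (v12 - v2))
    phi2 <- 0.5 * ((v2 - v0) + (v12 - v1))
    expect_equal(unname(att$phi[i, "f1"]), phi1, tolerance = 1e-4)
    expect_equal(unname(att$phi[i, "f2"]), phi2, tolerance = 1e-4)
    expect_equal(unname(att$phi_0[i]), v0, tolerance = 1e-4)
  }
})

test_that("AUROC is invariant to the monotone probability/log-odds transform", {
  d <- simulate_trial(small_params(n = 200, seed = 37))
  md <- model_definition("induction")
  run <- cross_val_predict_attribute(md, d, cheap_hp(), k_folds = 5, seed = 7)
  expect_equal(auroc(run$predictions$p_hat, run$predictions$y),
               auroc(run$predictions$f_hat, run$predictions$y),
               tolerance = 1e-12)
})
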