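# small-scale study conditions for unit tests (full scale lives in the
# acceptance tests)
small_params <- function(n = 300, seed = 42, ...) {
  trial_params(n_patients = n, seed = seed, ...)
}

# linear-logit generator variant: closed-form ground-truth effects
linear_params <- function(n = 300, seed = 42, beta_c = 0.8, beta_t = 0.8) {
  trial_params(
    n_patients = n, seed = seed,
    confounder_effect_params = list(
      induction = list(type = "linear", beta = beta_c),
      maintenance = list(type = "linear", beta = beta_c)),
    exposure_effect_params = list(
      induction = list(type = "linear", beta = beta_t),
      maintenance = list(type = "linear", beta = beta_t)))
}

# generator with every effect and all baseline variation switched off
null_params <- function(n, seed = 1, intercept = 0) {
  trial_params(
    n_patients = n, seed = seed,
    confounder_effect_params = list(
      induction = list(type = "linear", beta = 0),
      maintenance = list(type = "linear", beta = 0)),
    exposure_effect_params = list(
      induction = list(type = "linear", beta = 0),
      maintenance = list(type = "linear", beta = 0)),
    baseline_health_params = list(sd = 0),
    intercepts = list(induction = intercept, maintenance = intercept))
}

# fast boosted-tree settings for tests that only need a working model
cheap_hp <- function() {
  list(max_depth = 3, eta = 0.1, nrounds = 40, subsample = 1,
       colsample_bytree = 1, alpha = 0, lambda = 1, min_child_weight = 1)
}

# attribution columns of a run, as a matrix
phi_matrix <- function(run, modeldef) {
  as.matrix(run$attributions[, modeldef$features, drop = FALSE])
}
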