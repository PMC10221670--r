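#' Parameters of the two-stage trial generator
#'
#' Builds the full parameter set for [simulate_trial()]. The defaults encode
#' the study conditions of the package: a 2000-patient trial with two
#' randomization stages (induction, maintenance), standard-normal confounders
#' `c_I`/`c_M` that raise drug exposure on the active arm and act on outcome
#' through an inverted-U (non-monotonic) log-odds term, a saturating
#' Emax-shaped exposure effect, latent baseline health `h_I`, and nuisance
#' covariate blocks `x_I1..x_I4` / `x_M1..x_M3` with a seed-generated random
#' correlation structure and no causal path to outcome. Stage intercepts are
#' calibrated by 1-D root finding so that the expected response rates match
#' `target_rates` (40.2% induction, 78.2% maintenance by default), and the
#' induction randomization probability is set so the expected maintenance
#' cohort is 943 of 2000 patients.
#'
#' @param n_patients number of patients (>= 2).
#' @param seed integer global seed for the simulation stream.
#' @param randomization_prob_induction probability of the active arm at
#'   induction (`r_I = 1`); only active-arm patients continue to maintenance.
#' @param randomization_prob_maintenance probability of active arm at
#'   maintenance (`r_M = 1`).
#' @param covariate_covariance_spec list with elements `induction` and
#'   `maintenance`: either `NULL` (a random correlation matrix is generated
#'   from the seed) or a symmetric positive semi-definite matrix of the right
#'   dimension (4 and 3 respectively).
#' @param confounder_effect_params list with elements `induction` and
#'   `maintenance`, each either `list(type = "invu", b, mode)` for the
#'   inverted-U log-odds contribution `-b * (c - mode)^2`, or
#'   `list(type = "linear", beta)` for `beta * c`.
#' @param exposure_effect_params list with elements `induction` and
#'   `maintenance`, each either `list(type = "emax", emax, ec50)` for the
#'   saturating contribution `emax * t / (t + ec50)`, or
#'   `list(type = "linear", beta)`.
#' @param exposure_model_params list `list(slope, sd)`: on the active arm,
#'   exposure is the confounded lognormal `t = exp(slope * c + eps)`,
#'   `eps ~ N(0, sd^2)`; on placebo `t = 0`.
#' @param baseline_health_params list `list(sd)`: baseline latent health
#'   `h_I ~ N(0, sd^2)` on the log-odds scale.
#' @param intercepts list with elements `induction` and `maintenance`: either
#'   `NULL` (calibrate so the expected response rate equals the matching
#'   `target_rates` entry) or a fixed numeric log-odds intercept.
#' @param target_rates list with elements `induction` and `maintenance`:
#'   response rates used to calibrate `NULL` intercepts.
#' @return an object of class `trial_params`.
#' @seealso [simulate_trial()]
#' @export
trial_params <- function(n_patients = 2000,
                         seed = 1,
                         randomization_prob_induction = 943 / 2000,
                         randomization_prob_maintenance = 0.5,
                         covariate_covariance_spec = list(induction = NULL,
                                                          maintenance = NULL),
                         confounder_effect_params = list(
                           induction = list(type = "invu", b = 1.4, mode = 0.25),
                           maintenance = list(type = "invu", b = 1.2, mode = 0.25)),
                         exposure_effect_params = list(
                           induction = list(type = "emax", emax = 3.5, ec50 = 1),
                           maintenance = list(type = "emax", emax = 3.0, ec50 = 1)),
                         exposure_model_params = list(slope = 0.5, sd = 0.5),
                         baseline_health_params = list(sd = 0.5),
                         intercepts = list(induction = NULL, maintenance = NULL),
                         target_rates = list(induction = 0.402,
                                             maintenance = 0.782)) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 2) {
    stop("`n_patients` must be a single number >= 2", call. = FALSE)
  }
  for (p in c(randomization_prob_induction, randomization_prob_maintenance)) {
    if (!is.numeric(p) || p < 0 || p > 1) {
      stop("randomization probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  for (nm in c("induction", "maintenance")) {
    S <- covariate_covariance_spec[[nm]]
    d <- if (nm == "induction") 4L else 3L
    if (!is.null(S)) check_psd(S, d, nm)
    rt <- target_rates[[nm]]
    if (!is.null(rt) && (rt <= 0 || rt >= 1)) {
      stop("target rates must lie in (0, 1)", call. = FALSE)
    }
  }
  structure(list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    randomization_prob_induction = randomization_prob_induction,
    randomization_prob_maintenance = randomization_prob_maintenance,
    covariate_covariance_spec = covariate_covariance_spec,
    confounder_effect_params = confounder_effect_params,
    exposure_effect_params = exposure_effect_params,
    exposure_model_params = exposure_model_params,
    baseline_health_params = baseline_health_params,
    intercepts = intercepts,
    target_rates = target_rates
  ), class = "trial_params")
}

check_psd <- function(S, d, label) {
  if (!is.matrix(S) || nrow(S) != d || ncol(S) != d ||
      max(abs(S - t(S))) > 1e-8) {
    stop("covariance for the ", label,
         " covariate block must be a symmetric ", d, "x", d, " matrix",
         call. = FALSE)
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("covariance for the ", label,
         " covariate block is not positive semi-definite", call. = FALSE)
  }
  invisible(TRUE)
}

# seed-generated random correlation matrix (crossprod of a gaussian factor,
# rescaled to unit diagonal); always PSD by construction
random_correlation <- function(d, seed) {
  set.seed(seed)
  A <- matrix(stats::rnorm(d * (d + 2)), d + 2, d)
  stats::cov2cor(crossprod(A))
}

# additive log-odds contribution of a confounder
confounder_contrib <- function(c_val, spec) {
  switch(spec$type,
         invu = -spec$b * (c_val - spec$mode)^2,
         linear = spec$beta * c_val,
         stop("unknown confounder effect type: ", spec$type, call. = FALSE))
}

# additive log-odds contribution of exposure (zero at t = 0 for both forms)
exposure_contrib <- function(t_val, spec) {
  switch(spec$type,
         emax = spec$emax * t_val / (t_val + spec$ec50),
         linear = spec$beta * t_val,
         stop("unknown exposure effect type: ", spec$type, call. = FALSE))
}
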