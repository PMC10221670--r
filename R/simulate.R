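#' Simulate the two-stage confounded trial
#'
#' Generates the synthetic trial dataset. Per patient the induction stage
#' draws nuisance covariates `x_I1..x_I4` (correlated noise, no causal role),
#' a confounder `c_I ~ N(0,1)`, baseline latent health `h_I`, a randomization
#' indicator `r_I`, and exposure `t_I` (zero on placebo, confounded lognormal
#' on the active arm). Latent health at the end of induction is additive in
#' the log-odds domain,
#' `h_M = h_I + f_t(t_I) + f_c(c_I) + intercept_I`,
#' and the binary outcome is `y_1 ~ Bernoulli(sigma(h_M))` with `sigma` the
#' standard logistic function. Only active-arm patients (`r_I = 1`) continue
#' to maintenance, where the analogous draws produce `h_F`, `p2_true` and
#' `y_2`; maintenance fields are `NA` for everyone else.
#'
#' The per-variable log-odds contributions (`gt_t_I`, `gt_c_I`, `gt_t_M`,
#' `gt_c_M`) and the latent states are carried in the returned table so that
#' ground-truth operations never need to re-simulate.
#'
#' @param params a [trial_params()] object.
#' @return a `data.frame` of class `trial_dataset`, one row per patient, with
#'   attributes `params` and `intercepts` (the calibrated stage intercepts).
#' @examples
#' d <- simulate_trial(trial_params(n_patients = 200, seed = 7))
#' summarize_cohort(d)
#' @export
simulate_trial <- function(params) {
  if (!inherits(params, "trial_params")) params <- do.call(trial_params, params)
  n <- params$n_patients

  set.seed(stream_seed(params$seed, "trial/induction"))
  S_I <- params$covariate_covariance_spec$induction
  if (is.null(S_I)) {
    S_I <- random_correlation(4L, stream_seed(params$seed, "trial/corr_I"))
  }
  x_I <- MASS::mvrnorm(n, mu = rep(0, 4), Sigma = S_I)
  colnames(x_I) <- paste0("x_I", 1:4)
  c_I <- stats::rnorm(n)
  h_I <- stats::rnorm(n, 0, params$baseline_health_params$sd)
  r_I <- stats::rbinom(n, 1, params$randomization_prob_induction)
  em <- params$exposure_model_params
  t_I <- r_I * exp(em$slope * c_I + stats::rnorm(n, 0, em$sd))

  gt_t_I <- exposure_contrib(t_I, params$exposure_effect_params$induction)
  gt_c_I <- confounder_contrib(c_I, params$confounder_effect_params$induction)
  lat1 <- h_I + gt_t_I + gt_c_I
  int_I <- calibrate_intercept(lat1, params$intercepts$induction,
                               params$target_rates$induction)
  h_M <- lat1 + int_I
  p1_true <- stats::plogis(h_M)
  y_1 <- stats::rbinom(n, 1, p1_true)

  out <- data.frame(patient_id = seq_len(n), x_I, c_I = c_I, r_I = r_I,
                    t_I = t_I, h_I = h_I, gt_t_I = gt_t_I, gt_c_I = gt_c_I,
                    h_M = h_M, p1_true = p1_true, y_1 = y_1)

  # maintenance stage: active-arm induction patients only
  for (col in c(paste0("x_M", 1:3), "c_M", "r_M", "t_M", "gt_t_M", "gt_c_M",
                "h_F", "p2_true", "y_2")) out[[col]] <- NA_real_
  idx <- which(r_I == 1)
  int_M <- NA_real_
  if (length(idx) > 0) {
    set.seed(stream_seed(params$seed, "trial/maintenance"))
    nm <- length(idx)
    S_M <- params$covariate_covariance_spec$maintenance
    if (is.null(S_M)) {
      S_M <- random_correlation(3L, stream_seed(params$seed, "trial/corr_M"))
    }
    x_M <- MASS::mvrnorm(nm, mu = rep(0, 3), Sigma = S_M)
    if (nm == 1) x_M <- matrix(x_M, nrow = 1)
    c_M <- stats::rnorm(nm)
    r_M <- stats::rbinom(nm, 1, params$randomization_prob_maintenance)
    t_M <- r_M * exp(em$slope * c_M + stats::rnorm(nm, 0, em$sd))
    gt_t_M <- exposure_contrib(t_M, params$exposure_effect_params$maintenance)
    gt_c_M <- confounder_contrib(c_M, params$confounder_effect_params$maintenance)
    lat2 <- h_M[idx] + gt_t_M + gt_c_M
    int_M <- calibrate_intercept(lat2, params$intercepts$maintenance,
                                 params$target_rates$maintenance)
    h_F <- lat2 + int_M
    p2_true <- stats::plogis(h_F)
    out[idx, paste0("x_M", 1:3)] <- x_M
    out$c_M[idx] <- c_M
    out$r_M[idx] <- r_M
    out$t_M[idx] <- t_M
    out$gt_t_M[idx] <- gt_t_M
    out$gt_c_M[idx] <- gt_c_M
    out$h_F[idx] <- h_F
    out$p2_true[idx] <- p2_true
    out$y_2[idx] <- stats::rbinom(nm, 1, p2_true)
  }

  attr(out, "params") <- params
  attr(out, "intercepts") <- c(induction = int_I, maintenance = int_M)
  class(out) <- c("trial_dataset", "data.frame")
  out
}

# fixed intercept, or 1-D root finding so mean(sigma(lat + i)) hits the target
calibrate_intercept <- function(lat, fixed, target) {
  if (!is.null(fixed)) return(fixed)
  stats::uniroot(function(i) mean(stats::plogis(lat + i)) - target,
                 interval = c(-50, 50), tol = 1e-10)$root
}

#' Cohort counts and response rates
#'
#' @param dataset a [simulate_trial()] dataset.
#' @return a list with `n_total`, `induction_response_rate`, `n_maintenance`
#'   and `maintenance_response_rate` (`NA` when no patient entered
#'   maintenance).
#' @export
summarize_cohort <- function(dataset) {
  idx <- which(dataset$r_I == 1)
  list(n_total = nrow(dataset),
       induction_response_rate = mean(dataset$y_1),
       n_maintenance = length(idx),
       maintenance_response_rate =
         if (length(idx) == 0) NA_real_ else mean(dataset$y_2[idx]))
}

#' Ground-truth mean-subtracted marginal effects
#'
#' Returns, for each explanatory variable on the requested causal pathway,
#' its additive log-odds contribution in the generator evaluated per patient,
#' minus the mean of that contribution over the pathway's cohort. Non-causal
#' nuisance covariates have contribution exactly zero before subtraction.
#' Mean subtraction makes the columns directly comparable to SHAP values,
#' whose per-feature averages are deviations from the model's expected value.
#'
#' Pathways:
#' * `"induction"` — effects of `t_I` and `c_I` on `y_1`, over all patients;
#' * `"maintenance_only"` — effects of `t_M`, `c_M` and the baseline-health
#'   carry-over proxied by `y_1` (emitted as the `h_M` term of `h_F`) on
#'   `y_2`, over the maintenance cohort;
#' * `"maintenance_from_induction"` — effects of `t_I` and `c_I` (which reach
#'   `y_2` additively through `h_M`) over the maintenance cohort.
#'
#' @param dataset a [simulate_trial()] dataset (latent contributions are
#'   carried in its columns).
#' @param pathway one of `"induction"`, `"maintenance_only"`,
#'   `"maintenance_from_induction"`.
#' @return a `data.frame` with `patient_id` plus one mean-subtracted column
#'   per model feature; attribute `cohort` names the subtraction cohort.
#' @export
ground_truth_effects <- function(dataset, pathway) {
  pathway <- match.arg(pathway, c("induction", "maintenance_only",
                                  "maintenance_from_induction"))
  maint <- which(dataset$r_I == 1)
  if (pathway == "induction") {
    rows <- seq_len(nrow(dataset))
    eff <- data.frame(patient_id = dataset$patient_id[rows],
                      x_I1 = 0, x_I2 = 0, x_I3 = 0, x_I4 = 0,
                      c_I = dataset$gt_c_I[rows],
                      t_I = dataset$gt_t_I[rows])
  } else if (pathway == "maintenance_only") {
    rows <- maint
    if (length(rows) == 0) stop("maintenance cohort is empty", call. = FALSE)
    eff <- data.frame(patient_id = dataset$patient_id[rows],
                      x_M1 = 0, x_M2 = 0, x_M3 = 0,
                      c_M = dataset$gt_c_M[rows],
                      t_M = dataset$gt_t_M[rows],
                      y_1 = dataset$h_M[rows])
  } else {
    rows <- maint
    if (length(rows) == 0) stop("maintenance cohort is empty", call. = FALSE)
    eff <- data.frame(patient_id = dataset$patient_id[rows],
                      x_I1 = 0, x_I2 = 0, x_I3 = 0, x_I4 = 0,
                      c_I = dataset$gt_c_I[rows],
                      t_I = dataset$gt_t_I[rows])
  }
  for (col in setdiff(names(eff), "patient_id")) {
    eff[[col]] <- eff[[col]] - mean(eff[[col]])
  }
  attr(eff, "pathway") <- pathway
  attr(eff, "cohort") <- if (pathway == "induction") "all" else "maintenance"
  eff
}

#' Maximum theoretical discrimination of the true outcome probabilities
#'
#' AUROC of the generator's true probabilities (`sigma(h_M)` for stage 1,
#' `sigma(h_F)` for stage 2) against the realized binary outcomes. Because
#' outcomes are Bernoulli draws of these probabilities, no predictor can do
#' better in expectation; a fitted model scoring above this value on its own
#' training data is overfitting.
#'
#' @param dataset a [simulate_trial()] dataset.
#' @param stage 1 (induction, all patients) or 2 (maintenance cohort).
#' @return AUROC in `[0, 1]`.
#' @export
true_probability_auroc <- function(dataset, stage = 1) {
  stopifnot(stage %in% c(1, 2))
  if (stage == 1) {
    auroc(dataset$p1_true, dataset$y_1)
  } else {
    idx <- which(dataset$r_I == 1)
    auroc(dataset$p2_true[idx], dataset$y_2[idx])
  }
}
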