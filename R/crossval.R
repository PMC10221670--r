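# outcome-stratified fold assignment: shuffle within class, then deal folds
# round-robin over the class-grouped sequence, so folds are class-balanced
# and all k folds are non-empty whenever k <= n (including leave-one-out)
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  idx <- unlist(lapply(split(seq_along(labels), labels),
                       function(i) i[sample.int(length(i))]),
                use.names = FALSE)
  fold <- integer(length(labels))
  fold[idx] <- rep_len(seq_len(k), length(labels))
  fold
}

run_frame <- function(patient_id, labels, att, scope, fold = NA_integer_) {
  pred <- data.frame(patient_id = patient_id, y = labels, fold = fold,
                     p_hat = att$p_hat, f_hat = att$f_hat,
                     scope = scope, stringsAsFactors = FALSE)
  attm <- data.frame(patient_id = patient_id, fold = fold,
                     phi_0 = att$phi_0, att$phi, check.names = FALSE)
  list(predictions = pred, attributions = attm)
}

#' In-sample predictions and attributions
#'
#' Trains on the model's full cohort and scores/attributes the same
#' patients. Useful only as the negative control of the workflow: in-sample
#' predictions are biased toward the realized outcomes and under an untuned
#' flexible learner separate the classes perfectly.
#'
#' @param modeldef a [model_definition()].
#' @param dataset a [simulate_trial()] dataset.
#' @param hp hyperparameter list, default [untuned_hyperparams()].
#' @param seed integer seed.
#' @return list with `predictions` (patient_id, y, fold, p_hat, f_hat,
#'   scope) and `attributions` (patient_id, fold, phi_0, one column per
#'   feature), both with one row per cohort patient.
#' @export
in_sample_predict_attribute <- function(modeldef, dataset,
                                        hp = untuned_hyperparams(),
                                        seed = 1) {
  dsn <- extract_design(dataset, modeldef)
  model <- fit_classifier(dsn$features, dsn$labels, hp,
                          seed = stream_seed(seed, "fit/in_sample"))
  att <- attribute(model, dsn$features)
  run_frame(dsn$patient_id, dsn$labels, att, "in_sample")
}

#' Out-of-sample predictions and attributions via k-fold cross-validation
#'
#' Partitions the cohort into `k_folds` outcome-stratified folds; each fold
#' is scored and attributed by a model trained on the other folds only, so
#' every patient receives exactly one out-of-sample prediction and
#' attribution row. The base value `phi_0` is each fold-model's own expected
#' value, so the additive decomposition holds per patient against that
#' patient's fold model.
#'
#' @inheritParams in_sample_predict_attribute
#' @param k_folds number of folds (default 10); must not exceed cohort size.
#' @param max_retries number of fresh fold seeds to try if a training split
#'   ends up single-class.
#' @return as [in_sample_predict_attribute()], with `fold` filled in and
#'   `scope = "out_of_sample"`.
#' @export
cross_val_predict_attribute <- function(modeldef, dataset,
                                        hp = untuned_hyperparams(),
                                        k_folds = 10, seed = 1,
                                        max_retries = 10) {
  dsn <- extract_design(dataset, modeldef)
  n <- nrow(dsn$features)
  if (n < k_folds) stop("cohort smaller than the number of folds", call. = FALSE)

  fold <- NULL
  for (r in 0:max_retries) {
    cand <- stratified_folds(dsn$labels, k_folds,
                             stream_seed(seed, paste0("cv/folds/", r)))
    ok <- all(vapply(seq_len(k_folds), function(f) {
      length(unique(dsn$labels[cand != f])) == 2
    }, logical(1)))
    if (ok) { fold <- cand; break }
  }
  if (is.null(fold)) {
    stop("could not build folds with both classes in every training split",
         call. = FALSE)
  }

  p_hat <- f_hat <- phi_0 <- numeric(n)
  phi <- matrix(NA_real_, n, length(modeldef$features),
                dimnames = list(NULL, modeldef$features))
  for (f in seq_len(k_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    model <- fit_classifier(dsn$features[tr, , drop = FALSE], dsn$labels[tr],
                            hp, seed = stream_seed(seed, paste0("cv/fit/", f)))
    att <- attribute(model, dsn$features[te, , drop = FALSE])
    p_hat[te] <- att$p_hat; f_hat[te] <- att$f_hat
    phi_0[te] <- att$phi_0; phi[te, ] <- att$phi
  }
  run_frame(dsn$patient_id, dsn$labels,
            list(p_hat = p_hat, f_hat = f_hat, phi_0 = phi_0, phi = phi),
            "out_of_sample", fold = fold)
}
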