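#' Bayesian (sequential model-based) hyperparameter tuning
#'
#' Maximizes the mean k-fold cross-validated AUROC over the hyperparameter
#' box of [hyperparam_space()] using sequential model-based optimization:
#' a Latin-hypercube initial design, then a random-forest surrogate of the
#' CV objective with an expected-improvement acquisition evaluated over a
#' random candidate pool. Folds are outcome-stratified and held fixed across
#' candidates so that objective differences reflect the hyperparameters, not
#' resampling noise. Deterministic given `seed`.
#'
#' @param modeldef a [model_definition()].
#' @param dataset a [simulate_trial()] dataset.
#' @param space search space, see [hyperparam_space()]. Lower bounds must
#'   not exceed upper bounds; a space with all bounds equal is a singleton
#'   and is returned after a single evaluation.
#' @param n_iter total number of objective evaluations (default 25).
#' @param k_folds folds for the CV objective (default 5).
#' @param seed integer seed driving the initial design, fold assignment,
#'   candidate pool and surrogate.
#' @param n_init size of the Latin-hypercube initial design.
#' @param n_candidates size of the acquisition candidate pool per iteration.
#' @return the hyperparameter list of the best evaluated candidate, with
#'   attributes `cv_auroc` (its objective value) and `trace` (a data.frame
#'   of every evaluated candidate and its CV AUROC, in evaluation order).
#' @export
tune_hyperparameters <- function(modeldef, dataset, space = hyperparam_space(),
                                 n_iter = 25, k_folds = 5, seed = 1,
                                 n_init = max(4, floor(n_iter / 2.5)),
                                 n_candidates = 500) {
  if (any(space$lower > space$upper)) {
    stop("degenerate search space: lower bound exceeds upper bound",
         call. = FALSE)
  }
  d <- nrow(space)
  dsn <- extract_design(dataset, modeldef)
  fold <- stratified_folds(dsn$labels, k_folds, stream_seed(seed, "tune/folds"))

  cv_auroc <- function(hp) {
    aucs <- vapply(seq_len(k_folds), function(f) {
      tr <- which(fold != f); te <- which(fold == f)
      m <- fit_classifier(dsn$features[tr, , drop = FALSE], dsn$labels[tr],
                          hp, seed = stream_seed(seed, "tune/fit"))
      auroc(predict_prob(m, dsn$features[te, , drop = FALSE]), dsn$labels[te])
    }, numeric(1))
    mean(aucs)
  }

  singleton <- all(space$upper - space$lower <= 0)
  if (singleton) n_iter <- 1
  n_init <- min(n_init, n_iter)

  set.seed(stream_seed(seed, "tune/design"))
  U <- matrix(0.5, n_iter, d)
  if (n_init > 1) U[seq_len(n_init), ] <- lhs::randomLHS(n_init, d)
  score <- rep(NA_real_, n_iter)
  for (i in seq_len(n_init)) score[i] <- cv_auroc(decode_hyperparams(U[i, ], space))

  if (n_iter > n_init) {
    for (i in (n_init + 1):n_iter) {
      done <- seq_len(i - 1)
      sur <- ranger::ranger(
        y ~ ., data = data.frame(U[done, , drop = FALSE], y = score[done]),
        num.trees = 200, seed = stream_seed(seed, paste0("tune/surrogate/", i)))
      set.seed(stream_seed(seed, paste0("tune/candidates/", i)))
      cand <- matrix(stats::runif(n_candidates * d), n_candidates, d)
      pr <- stats::predict(sur, data.frame(cand), predict.all = TRUE)$predictions
      mu <- rowMeans(pr)
      sd_hat <- pmax(apply(pr, 1, stats::sd), 1e-9)
      best <- max(score[done])
      z <- (mu - best) / sd_hat
      ei <- (mu - best) * stats::pnorm(z) + sd_hat * stats::dnorm(z)
      U[i, ] <- cand[which.max(ei), ]
      score[i] <- cv_auroc(decode_hyperparams(U[i, ], space))
    }
  }

  trace <- do.call(rbind, lapply(seq_len(n_iter), function(i) {
    as.data.frame(decode_hyperparams(U[i, ], space))
  }))
  trace$cv_auroc <- score
  best_hp <- decode_hyperparams(U[which.max(score), ], space)
  validate_hyperparams(best_hp, space)
  attr(best_hp, "cv_auroc") <- max(score)
  attr(best_hp, "trace") <- trace
  best_hp
}
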