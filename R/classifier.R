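#' Untuned gradient-boosted tree configuration
#'
#' The learner's default settings (tree depth 6, learning rate 0.3, no
#' subsampling, L2 weight 1) with a boosting schedule long enough to
#' interpolate the training data — the overfitting regime whose consequences
#' the workflow is designed to expose. Recorded explicitly so that "untuned"
#' is reproducible.
#'
#' @return a named list of hyperparameters.
#' @export
untuned_hyperparams <- function() {
  list(max_depth = 6, eta = 0.3, nrounds = 200, subsample = 1,
       colsample_bytree = 1, alpha = 0, lambda = 1, min_child_weight = 1)
}

#' Hyperparameter search space
#'
#' Box bounds for the sequential model-based tuner. `scale = "log"`
#' parameters are searched log-uniformly; `type = "int"` parameters are
#' rounded to integers.
#'
#' @return a data.frame with one row per hyperparameter: `name`, `lower`,
#'   `upper`, `scale` (`"linear"`/`"log"`), `type` (`"num"`/`"int"`).
#' @export
hyperparam_space <- function() {
  data.frame(
    name  = c("max_depth", "eta", "nrounds", "subsample",
              "colsample_bytree", "alpha", "lambda"),
    lower = c(2, 0.01, 50, 0.5, 0.5, 0, 0),
    upper = c(10, 0.3, 500, 1, 1, 5, 5),
    scale = c("linear", "log", "linear", "linear", "linear", "linear", "linear"),
    type  = c("int", "num", "int", "num", "num", "num", "num"),
    stringsAsFactors = FALSE)
}

# map a point in the unit cube to a hyperparameter list
decode_hyperparams <- function(u, space) {
  hp <- list()
  for (i in seq_len(nrow(space))) {
    lo <- space$lower[i]; hi <- space$upper[i]
    v <- if (space$scale[i] == "log") {
      exp(log(lo) + u[i] * (log(hi) - log(lo)))
    } else {
      lo + u[i] * (hi - lo)
    }
    if (space$type[i] == "int") v <- as.integer(round(v))
    hp[[space$name[i]]] <- v
  }
  hp
}

validate_hyperparams <- function(hp, space = hyperparam_space()) {
  for (i in seq_len(nrow(space))) {
    v <- hp[[space$name[i]]]
    if (is.null(v)) next
    if (v < space$lower[i] - 1e-12 || v > space$upper[i] + 1e-12) {
      stop("hyperparameter ", space$name[i], " = ", v,
           " outside the search-space bounds [", space$lower[i], ", ",
           space$upper[i], "]", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Fit a gradient-boosted tree binary classifier
#'
#' Thin wrapper around `xgboost::xgb.train` with a logistic objective,
#' single-threaded and seeded for bit reproducibility. The fitted model
#' scores in both the probability and the raw log-odds (margin) domain and
#' supports exact per-feature additive TreeSHAP attributions.
#'
#' @param features numeric matrix (rows = patients, named columns).
#' @param labels 0/1 outcome vector; both classes must be present.
#' @param hp named list of hyperparameters (see [untuned_hyperparams()]);
#'   `nrounds` is the number of boosting rounds.
#' @param seed integer seed passed to the learner.
#' @return an object of class `er_classifier`.
#' @export
fit_classifier <- function(features, labels, hp = untuned_hyperparams(),
                           seed = 1) {
  if (!is.matrix(features) || nrow(features) < 2) {
    stop("`features` must be a matrix with at least 2 rows", call. = FALSE)
  }
  if (length(unique(labels)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  pars <- list(objective = "binary:logistic",
               max_depth = hp$max_depth, eta = hp$eta,
               subsample = hp$subsample %||% 1,
               colsample_bytree = hp$colsample_bytree %||% 1,
               alpha = hp$alpha %||% 0, lambda = hp$lambda %||% 1,
               min_child_weight = hp$min_child_weight %||% 1,
               nthread = 1, seed = as.integer(seed))
  booster <- xgboost::xgb.train(
    params = pars,
    data = xgboost::xgb.DMatrix(features, label = labels, nthread = 1),
    nrounds = hp$nrounds, verbose = 0)
  structure(list(booster = booster, feature_names = colnames(features),
                 hp = hp, seed = seed),
            class = "er_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predicted probabilities from a fitted classifier
#' @param model an `er_classifier`.
#' @param features numeric matrix with the model's feature columns.
#' @return vector of probabilities in (0, 1).
#' @export
predict_prob <- function(model, features) {
  stats::predict(model$booster,
                 xgboost::xgb.DMatrix(features, nthread = 1))
}

#' Raw log-odds score from a fitted classifier
#' @inheritParams predict_prob
#' @return vector of log-odds margins.
#' @export
predict_margin <- function(model, features) {
  stats::predict(model$booster, xgboost::xgb.DMatrix(features, nthread = 1),
                 outputmargin = TRUE)
}

#' Exact additive attributions in the log-odds domain
#'
#' Per-patient, per-feature TreeSHAP values plus the base value `phi_0` (the
#' model's expected log-odds). The emitted score `f_hat` is defined as
#' `phi_0 + sum(phi_v)` so the additive decomposition of the returned
#' artifacts is exact in double precision; it agrees with the learner's own
#' margin output to single-float accuracy.
#'
#' @inheritParams predict_prob
#' @return list with `phi` (matrix, one column per feature), `phi_0`
#'   (vector), `f_hat` (`phi_0 + rowSums(phi)`), `p_hat` (`plogis(f_hat)`).
#' @export
attribute <- function(model, features) {
  ctr <- stats::predict(model$booster,
                        xgboost::xgb.DMatrix(features, nthread = 1),
                        predcontrib = TRUE)
  k <- ncol(ctr)
  phi <- ctr[, -k, drop = FALSE]
  colnames(phi) <- model$feature_names
  phi_0 <- ctr[, k]
  f_hat <- phi_0 + rowSums(phi)
  list(phi = phi, phi_0 = phi_0, f_hat = f_hat,
       p_hat = stats::plogis(f_hat))
}
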