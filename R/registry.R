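#' The three causal-diagram-driven model definitions
#'
#' Variable selection for the exposure-response models is fixed by the causal
#' diagram of the trial, not learned from data. Three definitions are
#' registered:
#'
#' * `induction` — features `x_I1..x_I4, c_I, t_I`, outcome `y_1`, all
#'   patients; estimates the effect of `t_I` on `y_1` adjusting for the
#'   confounder `c_I`.
#' * `maintenance_only` — features `x_M1..x_M3, c_M, t_M, y_1`, outcome
#'   `y_2`, maintenance cohort; `y_1` proxies the unmeasured baseline health
#'   `h_M`.
#' * `maintenance_from_induction` — features `x_I1..x_I4, c_I, t_I`, outcome
#'   `y_2`, maintenance cohort. `y_1` is deliberately excluded: it mediates
#'   the `t_I -> y_2` pathway and conditioning on it would mask the effect
#'   being estimated.
#'
#' Latent variables (`h_I`, `h_M`, `h_F`) and true probabilities are treated
#' as unmeasurable and can never appear as features.
#'
#' @param name one of `"induction"`, `"maintenance_only"`,
#'   `"maintenance_from_induction"`.
#' @return an object of class `model_definition` with elements `name`,
#'   `features` (ordered), `outcome` and `cohort`.
#' @export
model_definition <- function(name) {
  defs <- list(
    induction = list(features = c(paste0("x_I", 1:4), "c_I", "t_I"),
                     outcome = "y_1", cohort = "all"),
    maintenance_only = list(features = c(paste0("x_M", 1:3), "c_M", "t_M", "y_1"),
                            outcome = "y_2", cohort = "maintenance"),
    maintenance_from_induction = list(features = c(paste0("x_I", 1:4), "c_I", "t_I"),
                                      outcome = "y_2", cohort = "maintenance"))
  if (!name %in% names(defs)) {
    stop("unknown model definition: '", name, "' (registered: ",
         paste(names(defs), collapse = ", "), ")", call. = FALSE)
  }
  d <- defs[[name]]
  new_model_definition(name, d$features, d$outcome, d$cohort,
                       non_standard = FALSE)
}

#' Names of the registered model definitions
#' @return character vector of length 3.
#' @export
model_names <- function() {
  c("induction", "maintenance_only", "maintenance_from_induction")
}

#' Build a custom (non-registered) model definition
#'
#' Extension point for sensitivity analyses, e.g. adding `c_I`/`t_I` to the
#' maintenance-stage model. Must be explicitly marked `non_standard = TRUE`;
#' the mediator-exclusion and latent-variable rules are still enforced.
#'
#' @param name definition label.
#' @param features ordered character vector of feature column names.
#' @param outcome `"y_1"` or `"y_2"`.
#' @param cohort `"all"` or `"maintenance"`.
#' @param non_standard must be `TRUE` to acknowledge the deviation from the
#'   registered causal-diagram definitions.
#' @return a `model_definition`.
#' @export
new_model_definition <- function(name, features, outcome, cohort,
                                 non_standard = TRUE) {
  if (!isFALSE(non_standard) && !isTRUE(non_standard)) {
    stop("`non_standard` must be TRUE or FALSE", call. = FALSE)
  }
  if (!name %in% model_names() && !isTRUE(non_standard)) {
    stop("custom model definitions require `non_standard = TRUE`",
         call. = FALSE)
  }
  outcome <- match.arg(outcome, c("y_1", "y_2"))
  cohort <- match.arg(cohort, c("all", "maintenance"))
  latent <- c("h_I", "h_M", "h_F", "p1_true", "p2_true",
              "gt_t_I", "gt_c_I", "gt_t_M", "gt_c_M")
  if (any(features %in% latent)) {
    stop("latent health states and true probabilities are unmeasurable and ",
         "cannot be used as features", call. = FALSE)
  }
  if (name == "maintenance_from_induction" && "y_1" %in% features) {
    stop("y_1 mediates the t_I -> y_2 pathway and must not be a feature of ",
         "the maintenance_from_induction model", call. = FALSE)
  }
  if (outcome %in% features) {
    stop("the outcome cannot also be a feature", call. = FALSE)
  }
  structure(list(name = name, features = features, outcome = outcome,
                 cohort = cohort, non_standard = non_standard),
            class = "model_definition")
}

#' Extract the design table and labels for a model definition
#'
#' Restricts the dataset to the definition's cohort, keeps the feature
#' columns in definition order, and returns the aligned outcome labels.
#'
#' @param dataset a [simulate_trial()] dataset (or any data.frame with the
#'   needed columns).
#' @param modeldef a [model_definition()].
#' @return list with `features` (numeric matrix, one column per feature),
#'   `labels` (0/1 vector) and `patient_id`.
#' @export
extract_design <- function(dataset, modeldef) {
  stopifnot(inherits(modeldef, "model_definition"))
  need <- c(modeldef$features, modeldef$outcome)
  missing_cols <- setdiff(need, names(dataset))
  if (length(missing_cols) > 0) {
    stop("dataset is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rows <- if (modeldef$cohort == "maintenance") {
    which(dataset$r_I == 1)
  } else {
    seq_len(nrow(dataset))
  }
  if (length(rows) == 0) stop("model cohort is empty", call. = FALSE)
  X <- as.matrix(as.data.frame(dataset)[rows, modeldef$features, drop = FALSE])
  storage.mode(X) <- "double"
  list(features = X,
       labels = as.numeric(dataset[[modeldef$outcome]][rows]),
       patient_id = dataset$patient_id[rows])
}
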