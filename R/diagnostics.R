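#' Area under the ROC curve
#'
#' Rank-based (Wilcoxon) AUROC: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, counting ties as one half.
#' Invariant under any strictly monotone transform of the scores, so it is
#' identical whether computed on predicted probabilities or log-odds.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels 0/1 outcome labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUROC undefined: labels contain a single class", call. = FALSE)
  }
  r <- rank(scores) # midranks handle ties with half credit
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Central 95% interval of a Poisson-binomial rate
#'
#' Given member-wise success probabilities `p`, computes the central
#' `level` interval of `S/n` where `S` is the sum of independent
#' `Bernoulli(p_i)`. Exact by convolution of the probability mass function
#' for small bins, normal approximation with mean `sum(p)` and variance
#' `sum(p(1-p))` for larger ones.
#'
#' @param p vector of success probabilities.
#' @param level interval mass (default 0.95).
#' @param exact_limit maximum `length(p)` for which the exact convolution is
#'   used (default 30).
#' @return `c(lower, upper)` on the rate scale.
#' @export
poisson_binomial_interval <- function(p, level = 0.95, exact_limit = 30) {
  n <- length(p)
  stopifnot(n >= 1, all(p >= 0 & p <= 1))
  alpha <- (1 - level) / 2
  if (n <= exact_limit) {
    pmf <- 1
    for (pi in p) pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
    cdf <- cumsum(pmf)
    lower <- (which(cdf >= alpha)[1] - 1) / n
    upper <- (which(cdf >= 1 - alpha)[1] - 1) / n
  } else {
    mu <- sum(p)
    sdv <- sqrt(sum(p * (1 - p)))
    z <- stats::qnorm(1 - alpha)
    lower <- max(0, (mu - z * sdv)) / n
    upper <- min(n, (mu + z * sdv)) / n
  }
  c(lower = lower, upper = upper)
}

#' Reliability (calibration) table
#'
#' Bins predicted probabilities into `n_bins` equal-width bins on (0, 1)
#' (the same schema as a histogram of the predictions) and compares each
#' bin's empirical outcome rate with the central 95% interval expected if
#' outcomes really were independent Bernoulli draws of the predicted
#' probabilities (a Poisson-binomial interval). A well-calibrated model has
#' most empirical rates inside their expected intervals.
#'
#' @param predictions either the `predictions` data.frame of
#'   [in_sample_predict_attribute()] / [cross_val_predict_attribute()] (the
#'   `p_hat` and `y` columns are used) or a numeric vector of predicted
#'   probabilities (then `labels` must be given).
#' @param labels 0/1 outcomes, required when `predictions` is a bare vector.
#' @param n_bins number of equal-width bins (default 10).
#' @param level interval mass (default 0.95).
#' @return data.frame with one row per bin: `bin`, `lower_bound`,
#'   `upper_bound`, `n`, `mean_p_hat`, `empirical_rate`, `expected_lower`,
#'   `expected_upper`, `inside` (empty bins carry `NA` statistics).
#' @export
reliability_table <- function(predictions, labels = NULL, n_bins = 10,
                              level = 0.95) {
  if (is.data.frame(predictions)) {
    labels <- predictions$y
    p_hat <- predictions$p_hat
  } else {
    p_hat <- predictions
  }
  if (is.null(labels) || length(labels) != length(p_hat) || length(p_hat) == 0) {
    stop("predictions and labels of matching positive length are required",
         call. = FALSE)
  }
  bin <- pmin(floor(p_hat * n_bins) + 1L, n_bins)
  out <- data.frame(bin = seq_len(n_bins),
                    lower_bound = (seq_len(n_bins) - 1) / n_bins,
                    upper_bound = seq_len(n_bins) / n_bins,
                    n = 0L, mean_p_hat = NA_real_, empirical_rate = NA_real_,
                    expected_lower = NA_real_, expected_upper = NA_real_,
                    inside = NA)
  for (b in seq_len(n_bins)) {
    i <- which(bin == b)
    out$n[b] <- length(i)
    if (length(i) == 0) next
    ci <- poisson_binomial_interval(p_hat[i], level = level)
    out$mean_p_hat[b] <- mean(p_hat[i])
    out$empirical_rate[b] <- mean(labels[i])
    out$expected_lower[b] <- ci[["lower"]]
    out$expected_upper[b] <- ci[["upper"]]
    out$inside[b] <- out$empirical_rate[b] >= ci[["lower"]] &
      out$empirical_rate[b] <= ci[["upper"]]
  }
  out
}

#' Compare in-sample and out-of-sample predictions and attributions
#'
#' Quantifies the bias of in-sample inference: per outcome class, the mean
#' difference between in-sample and out-of-sample predicted probabilities,
#' and per feature and class the mean attribution under both scopes. For a
#' model biased toward its training outcomes the prediction difference is
#' positive among responders and negative among non-responders, and the
#' class-mean attributions show the same sign pattern.
#'
#' @param in_run result of [in_sample_predict_attribute()].
#' @param out_run result of [cross_val_predict_attribute()] on the same
#'   cohort.
#' @return list with `prediction_bias` (class, n, mean_diff: mean of
#'   `p_in - p_out`) and `attribution_means` (feature, class, mean_in,
#'   mean_out, mean_diff).
#' @export
concordance_compare <- function(in_run, out_run) {
  pin <- in_run$predictions
  pout <- out_run$predictions
  if (!identical(pin$patient_id, pout$patient_id)) {
    stop("in-sample and out-of-sample runs cover different cohorts",
         call. = FALSE)
  }
  classes <- sort(unique(pin$y))
  pred_bias <- do.call(rbind, lapply(classes, function(cl) {
    i <- which(pin$y == cl)
    data.frame(class = cl, n = length(i),
               mean_diff = mean(pin$p_hat[i] - pout$p_hat[i]))
  }))
  feats <- setdiff(names(in_run$attributions), c("patient_id", "fold", "phi_0"))
  attr_means <- do.call(rbind, lapply(feats, function(v) {
    do.call(rbind, lapply(classes, function(cl) {
      i <- which(pin$y == cl)
      mi <- mean(in_run$attributions[[v]][i])
      mo <- mean(out_run$attributions[[v]][i])
      data.frame(feature = v, class = cl, mean_in = mi, mean_out = mo,
                 mean_diff = mi - mo)
    }))
  }))
  list(prediction_bias = pred_bias, attribution_means = attr_means)
}
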