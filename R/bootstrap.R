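boot_resample_engine <- function(modeldef, dataset, hp, B, seed, strategy,
                                 train_frac = NA_real_, max_retries = 20) {
  if (!is.numeric(B) || B < 1) stop("B must be >= 1", call. = FALSE)
  dsn <- extract_design(dataset, modeldef)
  n <- nrow(dsn$features)
  if (n < 10) stop("cohort too small for resampling inference", call. = FALSE)
  n_train <- if (strategy == "split_without_replacement") {
    if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1) {
      stop("train_frac must lie strictly between 0 and 1", call. = FALSE)
    }
    max(2L, round(train_frac * n))
  } else NA_integer_

  draws <- vector("list", B)
  train_rows <- vector("list", B)
  for (b in seq_len(B)) {
    found <- FALSE
    for (r in 0:max_retries) {
      set.seed(stream_seed(seed, paste0("boot/draw/", b, "/", r)))
      tr <- if (strategy == "with_replacement") {
        sample.int(n, n, replace = TRUE)
      } else {
        sample.int(n, n_train)
      }
      oob <- setdiff(seq_len(n), tr)
      if (length(oob) > 0 && length(unique(dsn$labels[tr])) == 2) {
        found <- TRUE
        break
      }
    }
    if (!found) {
      stop("could not draw a two-class training sample in iteration ", b,
           call. = FALSE)
    }
    train_rows[[b]] <- dsn$patient_id[tr]
    model <- fit_classifier(dsn$features[tr, , drop = FALSE], dsn$labels[tr],
                            hp, seed = stream_seed(seed, paste0("boot/fit/", b)))
    att <- attribute(model, dsn$features[oob, , drop = FALSE])
    draws[[b]] <- data.frame(iter = b, patient_id = dsn$patient_id[oob],
                             phi_0 = att$phi_0, att$phi, check.names = FALSE)
  }
  draws <- do.call(rbind, draws)

  feats <- modeldef$features
  qs <- function(x, q) unname(stats::quantile(x, q, type = 7))
  summ <- do.call(rbind, lapply(split(draws, draws$patient_id), function(d) {
    do.call(rbind, lapply(feats, function(v) {
      data.frame(patient_id = d$patient_id[1], feature = v,
                 mean = mean(d[[v]]),
                 lower = qs(d[[v]], 0.025), upper = qs(d[[v]], 0.975),
                 n_oob = nrow(d), stringsAsFactors = FALSE)
    }))
  }))
  never_oob <- setdiff(dsn$patient_id, unique(draws$patient_id))
  if (length(never_oob) > 0) {
    summ <- rbind(summ, do.call(rbind, lapply(never_oob, function(id) {
      data.frame(patient_id = id, feature = feats, mean = NA_real_,
                 lower = NA_real_, upper = NA_real_, n_oob = 0L,
                 stringsAsFactors = FALSE)
    })))
  }
  summ <- summ[order(summ$patient_id, match(summ$feature, feats)), ]
  rownames(summ) <- NULL

  structure(list(summary = summ, draws = draws, train_rows = train_rows,
                 B = as.integer(B), strategy = strategy,
                 train_frac = train_frac, seed = seed,
                 features = feats, model = modeldef$name,
                 patient_id = dsn$patient_id),
            class = "bootstrap_result")
}

#' Bootstrap (sampling with replacement) confidence intervals for attributions
#'
#' Each of `B` iterations draws N patients with replacement from the model's
#' cohort, trains a classifier on the draw, and computes log-odds
#' attributions for the out-of-bag patients (those absent from the draw,
#' about 36.8% of the cohort per iteration). Per patient and feature, the
#' attribution mean and percentile 95% CI (2.5th/97.5th percentiles) are
#' pooled over the iterations in which that patient was out-of-bag.
#' Hyperparameters are held fixed across iterations (tune once, then
#' bootstrap). Patients never out-of-bag are kept with `n_oob = 0` and `NA`
#' summaries rather than dropped.
#'
#' @param modeldef a [model_definition()].
#' @param dataset a [simulate_trial()] dataset.
#' @param hp hyperparameter list (typically the tuned set).
#' @param B number of bootstrap iterations (default 500).
#' @param seed integer seed; every draw and fit derives its own stream.
#' @return an object of class `bootstrap_result`: `summary` (long
#'   data.frame patient_id x feature with mean/lower/upper/n_oob), `draws`
#'   (per-iteration out-of-bag attribution rows, used for bin-level CIs),
#'   and the strategy metadata.
#' @export
bootstrap_attributions <- function(modeldef, dataset, hp, B = 500, seed = 1) {
  boot_resample_engine(modeldef, dataset, hp, B, seed, "with_replacement")
}

#' Split (sampling without replacement) comparator for bootstrap CIs
#'
#' Same pooling as [bootstrap_attributions()], but each iteration draws a
#' without-replacement train/test split of fraction `train_frac`; the test
#' part is attributed. Used as the comparator that shows why an arbitrary
#' split fraction under- or over-states uncertainty: a 90:10 split yields
#' unrealistically narrow CIs, a 10:90 split inflates them and estimates the
#' underlying relationships poorly.
#'
#' @inheritParams bootstrap_attributions
#' @param train_frac training fraction in (0, 1).
#' @export
split_attributions <- function(modeldef, dataset, hp, train_frac, B = 500,
                               seed = 1) {
  boot_resample_engine(modeldef, dataset, hp, B, seed,
                       "split_without_replacement", train_frac = train_frac)
}

#' Decile-binned bootstrap dependence summary
#'
#' Assigns the cohort to quantile bins of a feature (near-equal membership,
#' ties broken by patient order) and summarizes the bootstrap attributions
#' per bin: the bin mean attribution is the mean of member patients'
#' bootstrap means, and the bin 95% CI comes from the bootstrap replicates
#' of the bin mean (each iteration's mean over its out-of-bag members in
#' the bin, then 2.5/97.5 percentiles). For exposure features (`t_I`,
#' `t_M`) the zero-exposure (placebo) patients form their own bin ahead of
#' the quantile bins.
#'
#' @param result a `bootstrap_result`.
#' @param dataset the dataset the result was computed from.
#' @param feature one of the result's features.
#' @param n_bins number of quantile bins (default 10).
#' @return data.frame with one row per bin: `bin`, `placebo`, `n`,
#'   `median_value`, `mean_attr`, `lower`/`upper` (the bin-mean replicate
#'   CI) and `pool_lower`/`pool_upper` (percentiles of the bin members'
#'   pooled out-of-bag attribution values — the individual-level spread,
#'   always at least as wide); attribute `members` is the list of member
#'   patient ids per bin.
#' @export
bin_dependence <- function(result, dataset, feature, n_bins = 10) {
  stopifnot(inherits(result, "bootstrap_result"))
  if (!feature %in% result$features) {
    stop("feature '", feature, "' is not part of the bootstrapped model",
         call. = FALSE)
  }
  ids <- result$patient_id
  v <- dataset[[feature]][match(ids, dataset$patient_id)]

  members <- list()
  placebo <- logical(0)
  zero_bin <- feature %in% c("t_I", "t_M") && any(v == 0)
  pool_ids <- ids
  pool_v <- v
  if (zero_bin) {
    members <- list(ids[v == 0])
    placebo <- TRUE
    pool_ids <- ids[v > 0]
    pool_v <- v[v > 0]
  }
  # quantile bins with near-equal counts; ties broken by patient order
  ord <- order(pool_v, seq_along(pool_v))
  grp <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  grp <- pmin(grp, n_bins)
  for (b in seq_len(n_bins)) {
    members <- c(members, list(pool_ids[ord[grp == b]]))
    placebo <- c(placebo, FALSE)
  }

  draws <- result$draws
  summ <- result$summary[result$summary$feature == feature, ]
  out <- do.call(rbind, lapply(seq_along(members), function(b) {
    m <- members[[b]]
    vals <- v[match(m, ids)]
    sm <- summ$mean[match(m, summ$patient_id)]
    in_bin <- draws$patient_id %in% m
    rep_means <- tapply(draws[[feature]][in_bin], draws$iter[in_bin], mean)
    pooled <- stats::quantile(draws[[feature]][in_bin], c(0.025, 0.975),
                              type = 7)
    data.frame(bin = b, placebo = placebo[b], n = length(m),
               median_value = stats::median(vals),
               mean_attr = mean(sm, na.rm = TRUE),
               lower = unname(stats::quantile(rep_means, 0.025, type = 7)),
               upper = unname(stats::quantile(rep_means, 0.975, type = 7)),
               pool_lower = unname(pooled[1]), pool_upper = unname(pooled[2]))
  }))
  attr(out, "members") <- members
  attr(out, "feature") <- feature
  out
}

#' Coverage of ground-truth effects by binned bootstrap CIs
#'
#' For each bin of a [bin_dependence()] summary, computes the mean
#' ground-truth (mean-subtracted) effect of the bin's members and flags
#' whether it falls inside the bin's bootstrap 95% CI.
#'
#' @param binned a [bin_dependence()] result.
#' @param truth a [ground_truth_effects()] table for the matching pathway
#'   and cohort.
#' @return the binned table with columns `truth_mean` and `covered` added;
#'   attribute `n_covered` counts covered bins.
#' @export
ground_truth_agreement <- function(binned, truth) {
  feature <- attr(binned, "feature")
  if (!feature %in% names(truth)) {
    stop("ground-truth table has no column '", feature, "'", call. = FALSE)
  }
  members <- attr(binned, "members")
  all_m <- unlist(members)
  if (any(!all_m %in% truth$patient_id)) {
    stop("ground-truth table does not cover the binned cohort", call. = FALSE)
  }
  binned$truth_mean <- vapply(members, function(m) {
    mean(truth[[feature]][match(m, truth$patient_id)])
  }, numeric(1))
  binned$covered <- binned$truth_mean >= binned$lower &
    binned$truth_mean <= binned$upper
  attr(binned, "n_covered") <- sum(binned$covered)
  binned
}
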