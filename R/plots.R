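#' Plot a binned bootstrap dependence summary
#'
#' Mean attribution per bin against the bin's median feature value, with
#' vertical 95% CI bars; ground-truth bin means (when present, i.e. after
#' [ground_truth_agreement()]) are overlaid as crosses.
#'
#' @param binned a [bin_dependence()] (optionally with agreement columns).
#' @param main plot title.
#' @return invisibly, `NULL`. Base-graphics side effect.
#' @export
plot_dependence <- function(binned, main = attr(binned, "feature")) {
  ylim <- range(c(binned$lower, binned$upper, binned$truth_mean), na.rm = TRUE)
  graphics::plot(binned$median_value, binned$mean_attr, pch = 19,
                 ylim = ylim, xlab = attr(binned, "feature"),
                 ylab = "attribution (log-odds)", main = main)
  graphics::segments(binned$median_value, binned$lower,
                     binned$median_value, binned$upper, col = "grey40")
  if (!is.null(binned$truth_mean)) {
    graphics::points(binned$median_value, binned$truth_mean, pch = 4,
                     col = "red", cex = 1.2)
  }
  graphics::abline(h = 0, lty = 3)
  invisible(NULL)
}

#' Forest-style comparison of resampling strategies
#'
#' Draws per-bin (or per-patient subset) CI widths of several
#' `bootstrap_result` objects for one feature, to compare sampling with
#' replacement against fixed train/test splits.
#'
#' @param results named list of `bootstrap_result` objects.
#' @param feature feature name common to all results.
#' @return invisibly, a data.frame of median CI widths per strategy.
#' @export
plot_ci_width_comparison <- function(results, feature) {
  widths <- lapply(results, function(r) {
    s <- r$summary[r$summary$feature == feature & r$summary$n_oob > 0, ]
    s$upper - s$lower
  })
  med <- vapply(widths, stats::median, numeric(1))
  graphics::boxplot(widths, horizontal = TRUE, las = 1,
                    xlab = paste("95% CI width for", feature, "(log-odds)"))
  invisible(data.frame(strategy = names(results), median_width = unname(med)))
}
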