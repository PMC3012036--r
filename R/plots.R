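# Base-graphics summaries of the benchmark experiments.

#' Boxplot of NRMSE by imputation method
#'
#' One box per method (and per missing fraction when several were scanned).
#'
#' @param x An `rmse_experiment` from [run_rmse_experiment()].
#' @param fraction Optional single fraction to display.
#' @return Invisibly, `x`.
#' @export
plot_rmse <- function(x, fraction = NULL) {
  stopifnot(inherits(x, "rmse_experiment"))
  df <- x$results[!is.na(x$results$nrmse), ]
  if (!is.null(fraction)) df <- df[df$fraction == fraction, ]
  if (length(unique(df$fraction)) > 1L) {
    graphics::boxplot(nrmse ~ interaction(method, fraction, sep = " @ "),
                      data = df, las = 2, ylab = "normalized RMSE",
                      main = "Imputation error", cex.axis = 0.7)
  } else {
    graphics::boxplot(nrmse ~ method, data = df, las = 2,
                      ylab = "normalized RMSE", main = "Imputation error")
  }
  invisible(x)
}

#' Average spot variance after imputation
#'
#' Bar chart of the mean average variance per method and fraction, with the
#' complete-data average variance as a dashed reference line; every
#' imputation method is expected to fall at or below it.
#'
#' @param x An `rmse_experiment`.
#' @return Invisibly, `x`.
#' @export
plot_average_variance <- function(x) {
  stopifnot(inherits(x, "rmse_experiment"))
  agg <- summary(x)
  lab <- paste(agg$method, sprintf("%.0f%%", 100 * agg$fraction), sep = "\n")
  graphics::barplot(agg$avg_variance, names.arg = lab, las = 2,
                    cex.names = 0.7, ylab = "average spot variance",
                    main = "Variance shrinkage from imputation",
                    ylim = c(0, max(agg$avg_variance,
                                    x$complete_avg_variance) * 1.1))
  graphics::abline(h = x$complete_avg_variance, lty = 4)
  invisible(x)
}

#' Median discoveries per test and method
#'
#' Grouped bar chart of the median per-replicate discovery counts.
#'
#' @param x A `discovery_experiment` from [run_discovery_experiment()].
#' @return Invisibly, `x`.
#' @export
plot_median_discoveries <- function(x) {
  stopifnot(inherits(x, "discovery_experiment"))
  med <- x$median_discoveries
  tab <- with(med, tapply(median_discoveries, list(method, test), identity))
  graphics::barplot(tab, beside = TRUE, legend.text = rownames(tab),
                    ylab = "median discoveries",
                    main = sprintf("Discoveries at alpha = %.2f", x$alpha),
                    las = 2, args.legend = list(x = "topright", cex = 0.8))
  invisible(x)
}
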