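#' Mean-normalize a spot matrix
#'
#' Divides every spot volume by the total observed volume of its gel, the
#' standard correction for between-gel differences in protein loading and
#' staining.  Missing cells are preserved and excluded from the gel totals,
#' so the observed volumes of each gel sum to exactly 1 afterwards.  The
#' operation is idempotent.
#'
#' @param x A [spot_matrix()].
#' @return A mean-normalized [spot_matrix()].
#' @export
mean_normalize <- function(x) {
  stopifnot(inherits(x, "spot_matrix"))
  totals <- colSums(x$values, na.rm = TRUE)
  all_missing <- colSums(!is.na(x$values)) == 0L
  if (any(all_missing)) {
    stop_validation("gel(s) with no observed spots: %s",
                    paste(colnames(x$values)[all_missing], collapse = ", "))
  }
  if (any(totals <= 0)) {
    stop_validation("gel(s) with non-positive total volume: %s",
                    paste(colnames(x$values)[totals <= 0], collapse = ", "))
  }
  spot_matrix(sweep(x$values, 2L, totals, "/"), x$design)
}

#' Per-gel missingness summary
#'
#' Counts missing spots per gel, summarises them per group, and compares the
#' two groups' per-gel counts with a Welch t test --- the check that
#' missingness is unrelated to treatment.  When both groups have identical
#' constant counts (no variance, no mean difference) the p-value is defined
#' as 1.
#'
#' @param x A [spot_matrix()].
#' @return An object of class `"missingness_summary"`: list with
#'   `per_gel` (named counts), `group_mean`, `group_sd` (named by group),
#'   and `between_group_p`.
#' @export
missingness_by_gel <- function(x) {
  stopifnot(inherits(x, "spot_matrix"))
  counts <- colSums(is.na(x$values))
  by_group <- split(counts, x$design$group)
  res <- welch_t(by_group[[1L]], by_group[[2L]])
  structure(list(
    per_gel = counts,
    group_mean = vapply(by_group, mean, numeric(1)),
    group_sd = vapply(by_group, sd, numeric(1)),
    between_group_p = res$p_value
  ), class = "missingness_summary")
}

#' @export
print.missingness_summary <- function(x, ...) {
  cat("missing spots per gel:\n")
  print(x$per_gel)
  for (g in names(x$group_mean)) {
    cat(sprintf("  group %s: mean %.2f, sd %.2f\n",
                g, x$group_mean[[g]], x$group_sd[[g]]))
  }
  cat(sprintf("  Welch t between groups: p = %.4g\n", x$between_group_p))
  invisible(x)
}

#' Complete-spot counts by intensity quartile
#'
#' Bins spots into quartiles of their mean observed intensity and counts,
#' per quartile, how many spots have no missing cells.  With
#' intensity-dependent missingness the complete counts rise from the dimmest
#' (Q1) to the brightest (Q4) quartile.  Quartile boundaries are the
#' empirical 25/50/75 percentiles; a spot whose mean lies exactly on a
#' boundary goes to the lower quartile.
#'
#' @param x A [spot_matrix()] with at least 4 spots.
#' @return Data frame with columns `quartile` (`Q1`..`Q4`), `n_spots`, and
#'   `n_complete`.  `n_spots` sums to the number of spots.
#' @export
completeness_by_quartile <- function(x) {
  stopifnot(inherits(x, "spot_matrix"))
  if (n_spots(x) < 4L) stop_validation("need at least 4 spots for quartiles")
  m <- rowMeans(x$values, na.rm = TRUE)
  q <- quantile(m, c(0.25, 0.5, 0.75), names = FALSE)
  quartile <- 1L + (m > q[1L]) + (m > q[2L]) + (m > q[3L])
  complete <- rowSums(is.na(x$values)) == 0L
  data.frame(
    quartile = paste0("Q", 1:4),
    n_spots = tabulate(quartile, nbins = 4L),
    n_complete = vapply(1:4, function(k) sum(complete[quartile == k]), integer(1))
  )
}

#' Keep spots observed in a majority of gels
#'
#' Drops spots with too many missing cells before any imputation, limiting
#' how much of the analysis rests on interpolated values.  By default the
#' rule is applied within each group: a spot is kept only when it is
#' observed in strictly more than half the gels of *both* groups (so with
#' 6 gels per group a spot needs at least 4 observations per group).  Set
#' `per_group = FALSE` for a whole-matrix majority instead.
#'
#' @param x A [spot_matrix()].
#' @param per_group Apply the strict majority within each group (default)
#'   rather than across all gels.
#' @return A [spot_matrix()] with the retained spots, original order kept.
#'   A warning (not an error) is raised if no spot survives.
#' @export
filter_majority_present <- function(x, per_group = TRUE) {
  stopifnot(inherits(x, "spot_matrix"))
  obs <- !is.na(x$values)
  if (per_group) {
    cols <- group_columns(x$design)
    keep <- Reduce(`&`, lapply(cols, function(j) {
      rowSums(obs[, j, drop = FALSE]) > length(j) / 2
    }))
  } else {
    keep <- rowSums(obs) > ncol(obs) / 2
  }
  if (!any(keep)) {
    warning("no spot is observed in a majority of gels; returning 0 spots")
  }
  spot_matrix(x$values[keep, , drop = FALSE], x$design)
}

#' Average spot variance of a complete matrix
#'
#' The mean over spots of each spot's across-gel sample variance (n-1
#' denominator).  Used to quantify the variance shrinkage that imputation by
#' within-row summaries induces.
#'
#' @param x A complete [spot_matrix()].
#' @return Numeric scalar.
#' @export
average_variance <- function(x) {
  stopifnot(inherits(x, "spot_matrix"))
  if (!is_complete(x)) stop_validation("average_variance needs a complete matrix")
  mean(row_variances(x$values))
}
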