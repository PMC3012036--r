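# Multiple-testing selection procedures.  All take a vector of p-values and
# return the integer indices of rejected hypotheses (named when the input
# is named), sorted increasingly.

check_pvalues <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop_validation("p-values must all lie in [0, 1] with no NA")
  }
}

#' Selection configuration
#'
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param procedure `"per_comparison"`, `"gfwer"`, or `"bh_fdr"`.
#' @param k_allow For gFWER: number of tolerated false positives (default 0,
#'   i.e. ordinary family-wise control).
#' @return A list of class `"selection_config"`.
#' @export
selection_config <- function(alpha = 0.05,
                             procedure = c("per_comparison", "gfwer", "bh_fdr"),
                             k_allow = 0L) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1)) {
    stop_validation("alpha must lie strictly between 0 and 1")
  }
  if (!is_count(k_allow, 0L)) stop_validation("k_allow must be >= 0")
  structure(list(alpha = alpha, procedure = match.arg(procedure),
                 k_allow = as.integer(k_allow)),
            class = "selection_config")
}

#' Per-comparison selection
#'
#' Rejects every hypothesis with `p < alpha` (strict inequality), i.e. no
#' multiplicity correction.  Appropriate only for comparing procedures, not
#' for claiming discoveries.
#'
#' @param pvals Numeric vector of p-values.
#' @param alpha Significance level (default 0.05).
#' @return Sorted integer indices of rejections.
#' @export
select_per_comparison <- function(pvals, alpha = 0.05) {
  check_pvalues(pvals)
  which(pvals < alpha)
}

#' gFWER selection by augmentation
#'
#' Controls the generalized family-wise error rate, the probability of more
#' than `k_allow` false rejections: first apply Holm's step-down FWER
#' procedure at level `alpha`, then augment the rejection set with the
#' `k_allow` smallest remaining p-values (ties broken by input order).
#' `k_allow = 0` is exactly Holm.
#'
#' @param pvals Numeric vector of p-values.
#' @param alpha Significance level (default 0.05).
#' @param k_allow Number of tolerated false positives (default 0).
#' @return Sorted integer indices of rejections.
#' @export
select_gfwer <- function(pvals, alpha = 0.05, k_allow = 0L) {
  check_pvalues(pvals)
  base <- which(p.adjust(pvals, method = "holm") <= alpha)
  if (k_allow > 0L) {
    rest <- setdiff(order(pvals), base)
    base <- c(base, rest[seq_len(min(k_allow, length(rest)))])
  }
  sort(base)
}

#' Benjamini-Hochberg FDR selection
#'
#' Step-up control of the false discovery rate at level `alpha`; the
#' comparator that gFWER control is usually weighed against when fewer
#' than ~1000 hypotheses are tested.
#'
#' @param pvals Numeric vector of p-values.
#' @param alpha Significance level (default 0.05).
#' @return Sorted integer indices of rejections.
#' @export
select_bh_fdr <- function(pvals, alpha = 0.05) {
  check_pvalues(pvals)
  which(p.adjust(pvals, method = "BH") <= alpha)
}

#' Apply a configured selection procedure
#'
#' @param pvals Numeric vector of p-values.
#' @param config A [selection_config()].
#' @return Sorted integer indices of rejections.
#' @export
select_spots <- function(pvals, config = selection_config()) {
  switch(config$procedure,
         per_comparison = select_per_comparison(pvals, config$alpha),
         gfwer = select_gfwer(pvals, config$alpha, config$k_allow),
         bh_fdr = select_bh_fdr(pvals, config$alpha))
}

#' Tabulate a selection for export
#'
#' @param pvals Named (or unnamed) p-value vector.
#' @param config A [selection_config()].
#' @return Data frame with `spot_id`, `p_value`, `rejected`, `procedure`,
#'   `alpha`, `k_allow` --- the layout written by [run_pipeline()].
#' @export
selection_table <- function(pvals, config = selection_config()) {
  rej <- select_spots(pvals, config)
  data.frame(
    spot_id = names(pvals) %||% as.character(seq_along(pvals)),
    p_value = unname(pvals),
    rejected = seq_along(pvals) %in% rej,
    procedure = config$procedure,
    alpha = config$alpha,
    k_allow = config$k_allow,
    stringsAsFactors = FALSE
  )
}
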