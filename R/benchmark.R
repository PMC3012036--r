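# Monte-Carlo benchmarking: (1) mask -> impute -> normalized RMSE and
# average variance; (2) mask -> impute -> test -> per-comparison selection,
# consensus discoveries and overlap between methods and the complete data.

#' Normalized RMSE of an imputation against a removal record
#'
#' Root mean square error over the masked cells, normalized to be
#' scale-free.  The default divisor is the standard deviation of *all*
#' true cells of the source matrix (reconstructed from the result and the
#' record), which is identical for every mask drawn from one source, so
#' NRMSE means are comparable across missing fractions.  `"masked_sd"`
#' divides by the SD of the masked cells' true values instead and
#' `"mean"` by their mean; both are per-draw quantities — at a 5% fraction
#' of a 70 x 12 matrix the masked-SD divisor is estimated from 42 cells
#' and its sampling noise inflates mean NRMSE by ~10% (Jensen bias on
#' 1/sd), a bias that shrinks with the fraction and can mask genuine
#' fraction trends.  If the divisor is 0 the raw RMSE is returned with
#' attribute `unnormalized = TRUE`.
#'
#' @param record A `removal_record` from [remove_at_random()] or
#'   [remove_intensity_dependent()].
#' @param result An `imputation_result` whose imputed cells cover the
#'   record's cells.
#' @param divisor `"source_sd"` (default), `"masked_sd"`, or `"mean"`.
#' @return Non-negative numeric scalar.
#' @export
normalized_rmse <- function(record, result,
                            divisor = c("source_sd", "masked_sd", "mean")) {
  stopifnot(inherits(record, "removal_record"),
            inherits(result, "imputation_result"))
  divisor <- match.arg(divisor)
  key_rec <- paste(record$spot_id, record$gel_id, sep = "\r")
  key_imp <- paste(result$imputed_cells$spot_id, result$imputed_cells$gel_id,
                   sep = "\r")
  pos <- match(key_rec, key_imp)
  if (anyNA(pos)) {
    stop_validation("%d masked cell(s) missing from the imputation result",
                    sum(is.na(pos)))
  }
  imputed <- result$imputed_cells$value[pos]
  truth <- record$true_value
  rmse <- sqrt(mean((imputed - truth)^2))
  d <- switch(divisor,
    masked_sd = sd(truth),
    mean = mean(truth),
    source_sd = {
      src <- result$matrix$values
      ij <- cbind(match(record$spot_id, rownames(src)),
                  match(record$gel_id, colnames(src)))
      src[ij] <- record$true_value
      sd(src)
    })
  if (!is.finite(d) || d == 0) {
    return(structure(rmse, unnormalized = TRUE))
  }
  rmse / d
}

#' Imputation-accuracy experiment (masked-cell NRMSE and average variance)
#'
#' For each replicate and missing fraction, masks cells completely at
#' random from the complete source matrix (replicate `r` uses seed
#' `base_seed + r`, and the identical mask is shared by every method, so
#' method contrasts are paired), imputes with each method, and records the
#' normalized RMSE and the average spot variance of the completed matrix.
#' With `nested = TRUE` (the default) the masks of one replicate are nested
#' across fractions --- the 5% mask is a prefix of the 10% mask and so on
#' --- which pairs the fraction contrast as well; a prefix of a uniform
#' draw is itself uniform, and the retention constraint only needs to hold
#' at the largest fraction.  A method failing on a replicate is recorded as
#' `NA` with the reason; the run continues.
#'
#' @param source A complete [spot_matrix()].
#' @param methods Character vector of registry labels (see
#'   [imputation_methods()]).
#' @param fractions Missing fractions to scan (default `c(0.05, 0.10, 0.20)`).
#' @param n_reps Replicates per fraction (default 100).
#' @param base_seed Integer base seed (default 1).
#' @param divisor NRMSE divisor, see [normalized_rmse()].
#' @param nested Nest the masks across fractions within a replicate
#'   (default `TRUE`).
#' @return An object of class `"rmse_experiment"`: list with `results`
#'   (data frame: `method`, `fraction`, `replicate`, `seed`, `nrmse`,
#'   `avg_variance`, `note`), `complete_avg_variance`, and the call
#'   parameters.
#' @export
run_rmse_experiment <- function(source, methods,
                                fractions = c(0.05, 0.10, 0.20),
                                n_reps = 100L, base_seed = 1L,
                                divisor = c("source_sd", "masked_sd", "mean"),
                                nested = TRUE) {
  stopifnot(inherits(source, "spot_matrix"))
  divisor <- match.arg(divisor)
  if (!is_complete(source)) stop_validation("source matrix must be complete")
  cav <- average_variance(source)
  nc <- length(source$values)
  f_max <- max(fractions)
  rows <- vector("list", length(fractions) * n_reps * length(methods))
  k <- 0L
  for (r in seq_len(n_reps)) {
    seed_r <- base_seed + r
    if (nested) {
      draw <- draw_mcar_indices(source, round(f_max * nc), seed_r,
                                "per_group", 2L, 10000L)
    }
    for (f in fractions) {
      if (nested) {
        idx <- sort(draw[seq_len(round(f * nc))])
        mk <- mask_cells(source, idx)
        rem <- list(matrix = mk$matrix,
                    record = new_removal_record(mk$spot_id, mk$gel_id,
                                                mk$truth, f, seed_r))
      } else {
        rem <- remove_at_random(source, f, seed = seed_r)
      }
      for (m in methods) {
        k <- k + 1L
        row <- data.frame(method = m, fraction = f, replicate = r,
                          seed = seed_r, nrmse = NA_real_,
                          avg_variance = NA_real_, note = "",
                          stringsAsFactors = FALSE)
        res <- tryCatch(
          suppressWarnings(impute_spots(rem$matrix, m)),
          error = function(e) conditionMessage(e))
        if (is.character(res)) {
          row$note <- res
        } else {
          row$nrmse <- as.numeric(normalized_rmse(rem$record, res, divisor))
          row$avg_variance <- mean(row_variances(res$matrix$values))
        }
        rows[[k]] <- row
      }
    }
  }
  structure(list(results = do.call(rbind, rows),
                 complete_avg_variance = cav,
                 methods = methods, fractions = fractions,
                 n_reps = n_reps, base_seed = base_seed, divisor = divisor,
                 nested = nested),
            class = "rmse_experiment")
}

#' @export
print.rmse_experiment <- function(x, ...) {
  cat(sprintf("rmse_experiment: %d methods x %d fractions x %d replicates\n",
              length(x$methods), length(x$fractions), x$n_reps))
  print(summary(x))
  invisible(x)
}

#' @export
summary.rmse_experiment <- function(object, ...) {
  agg <- aggregate(cbind(nrmse, avg_variance) ~ method + fraction,
                   data = object$results, FUN = mean, na.action = stats::na.omit)
  agg <- agg[order(agg$fraction, agg$method), ]
  rownames(agg) <- NULL
  agg
}

#' Consensus discoveries over Monte-Carlo replicates
#'
#' A spot counts as a consensus discovery when its p-value is below `alpha`
#' in at least `ceiling(min_fraction * n_reps)` replicates --- by default
#' in at least half of the simulated masked-and-imputed datasets.
#'
#' @param pvals Replicates x spots matrix of p-values.
#' @param alpha Significance level (default 0.05).
#' @param min_fraction Required fraction of replicates (default 0.5).
#' @return Integer indices (named if `pvals` has column names).
#' @export
consensus_discoveries <- function(pvals, alpha = 0.05, min_fraction = 0.5) {
  stopifnot(is.matrix(pvals))
  if (anyNA(pvals)) stop_validation("p-value grid must be complete")
  need <- ceiling(min_fraction * nrow(pvals))
  which(colSums(pvals < alpha) >= need)
}

#' Region counts of overlapping discovery sets
#'
#' Partitions the union of 2--4 labelled sets into its inclusion-exclusion
#' regions (as drawn in a Venn diagram) and counts the members of each.
#' Region names join the labels with `&`; counts over all regions sum to
#' the size of the union.
#'
#' @param sets Named list of 2--4 vectors.
#' @return Named integer vector over all non-empty label combinations.
#' @export
overlap_summary <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 4L) {
    stop_validation("overlap_summary needs 2 to 4 labelled sets")
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop_validation("sets must be named")
  }
  universe <- unique(unlist(lapply(sets, unique), use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 0L) {
    member <- matrix(logical(0), 0L, length(sets),
                     dimnames = list(NULL, names(sets)))
  }
  if (length(universe) == 1L) member <- matrix(member, 1L)
  labs <- names(sets)
  out <- integer(0)
  for (size in seq_along(labs)) {
    for (combo in asplit(combn(seq_along(labs), size), 2L)) {
      inside <- rowSums(member[, combo, drop = FALSE]) == size &
        rowSums(member[, -combo, drop = FALSE]) == 0
      out[paste(labs[combo], collapse = "&")] <- sum(inside)
    }
  }
  out
}

#' Median number of discoveries across replicates
#'
#' @param sets List of per-replicate rejection sets (any vectors); their
#'   lengths are summarised.
#' @return Numeric scalar: the median set size (mean of the middle two for
#'   an even count).
#' @export
median_discoveries <- function(sets) {
  if (length(sets) < 1L) stop_validation("need at least one replicate")
  median(lengths(sets))
}

#' Discovery-agreement experiment
#'
#' The second Monte-Carlo protocol: per replicate, mask `fraction` of the
#' complete source at random (seed `base_seed + r`), impute with every
#' method, apply every test spot-wise, and select at the per-comparison
#' level `alpha`.  Each test also runs once on the unmasked source (the
#' "complete" arm).  Summaries: per-replicate discovery counts, median
#' discoveries per test/method, consensus discovery sets (significant in at
#' least `min_fraction` of replicates), and --- for up to three methods ---
#' the Venn region counts of the complete-data set against the methods'
#' consensus sets.
#'
#' @param source A complete [spot_matrix()].
#' @param methods Imputation registry labels.
#' @param tests Test labels (see [test_labels()]).
#' @param fraction Missing fraction per replicate (default 0.10).
#' @param n_reps Replicates (default 20).
#' @param alpha Per-comparison level (default 0.05).
#' @param base_seed Integer base seed (default 1).
#' @param test_config A [resampling_config()] template; its seed is reset
#'   per replicate.
#' @param min_fraction Consensus threshold (default 0.5).
#' @return An object of class `"discovery_experiment"`: list with
#'   `counts` (data frame: `test`, `method`, `replicate`, `n_discoveries`),
#'   `complete_sets` (per test, indices discovered on the complete data),
#'   `consensus` (nested list test -> method -> indices), `overlap`
#'   (per test, the [overlap_summary()] of complete + consensus sets, or
#'   `NULL` when more than 3 methods), `median_discoveries` (data frame),
#'   and the call parameters.
#' @export
run_discovery_experiment <- function(source, methods, tests,
                                     fraction = 0.10, n_reps = 20L,
                                     alpha = 0.05, base_seed = 1L,
                                     test_config = resampling_config(),
                                     min_fraction = 0.5) {
  stopifnot(inherits(source, "spot_matrix"))
  if (!is_complete(source)) stop_validation("source matrix must be complete")
  ns <- n_spots(source)
  spot_ids <- rownames(source$values)

  complete_sets <- list()
  for (tl in tests) {
    cfg <- test_config; cfg$seed <- base_seed
    tt <- test_matrix(source, tl, cfg)
    complete_sets[[tl]] <- select_per_comparison(tt$p_value, alpha)
  }

  pgrid <- array(NA_real_,
                 dim = c(n_reps, ns, length(tests), length(methods)),
                 dimnames = list(NULL, spot_ids, tests, methods))
  rows <- list()
  for (r in seq_len(n_reps)) {
    seed_r <- base_seed + r
    rem <- remove_at_random(source, fraction, seed = seed_r)
    for (m in methods) {
      imp <- tryCatch(suppressWarnings(impute_spots(rem$matrix, m)),
                      error = function(e) NULL)
      for (tl in tests) {
        if (is.null(imp)) next
        cfg <- test_config; cfg$seed <- seed_r
        tt <- test_matrix(imp$matrix, tl, cfg)
        pgrid[r, , tl, m] <- tt$p_value
        rows[[length(rows) + 1L]] <-
          data.frame(test = tl, method = m, replicate = r,
                     n_discoveries = length(select_per_comparison(tt$p_value,
                                                                  alpha)),
                     stringsAsFactors = FALSE)
      }
    }
  }
  counts <- do.call(rbind, rows)

  consensus <- lapply(tests, function(tl) {
    out <- lapply(methods, function(m) {
      pm <- pgrid[, , tl, m, drop = FALSE]
      dim(pm) <- c(n_reps, ns)
      colnames(pm) <- spot_ids
      if (anyNA(pm)) return(integer(0))
      consensus_discoveries(pm, alpha, min_fraction)
    })
    names(out) <- methods
    out
  })
  names(consensus) <- tests

  overlap <- lapply(tests, function(tl) {
    if (length(methods) > 3L) return(NULL)
    overlap_summary(c(list(complete = complete_sets[[tl]]),
                      consensus[[tl]]))
  })
  names(overlap) <- tests

  med <- aggregate(n_discoveries ~ test + method, data = counts, FUN = median)
  names(med)[names(med) == "n_discoveries"] <- "median_discoveries"

  structure(list(counts = counts, complete_sets = complete_sets,
                 consensus = consensus, overlap = overlap,
                 median_discoveries = med,
                 methods = methods, tests = tests, fraction = fraction,
                 n_reps = n_reps, alpha = alpha, base_seed = base_seed,
                 min_fraction = min_fraction),
            class = "discovery_experiment")
}

#' @export
print.discovery_experiment <- function(x, ...) {
  cat(sprintf("discovery_experiment: %d tests x %d methods x %d replicates (%.0f%% masked)\n",
              length(x$tests), length(x$methods), x$n_reps, 100 * x$fraction))
  print(x$median_discoveries)
  invisible(x)
}
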