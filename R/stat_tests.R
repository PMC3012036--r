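# Six per-spot two-group tests.  All return a "spot_test" list with fields
# statistic, p_value, test_label, and a detail list.  All handle the
# zero-variance degenerate case explicitly so matrix-wide application never
# drops spots silently.

new_spot_test <- function(statistic, p_value, test_label, detail = list()) {
  structure(list(statistic = statistic, p_value = p_value,
                 test_label = test_label, detail = detail),
            class = "spot_test")
}

#' @export
print.spot_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n",
              x$test_label, x$statistic, x$p_value))
  invisible(x)
}

check_samples <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop_validation("each sample needs at least 2 observations (got %d and %d)",
                    length(a), length(b))
  }
  if (anyNA(a) || anyNA(b)) stop_validation("samples must not contain NA")
}

# Welch statistic with explicit degenerate handling; shared by several tests
welch_stat <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  d <- mean(a) - mean(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (d == 0) {
      return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    }
    return(list(t = sign(d) * Inf, df = NA_real_, p = 0, degenerate = TRUE))
  }
  t <- d / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df), degenerate = FALSE)
}

#' Welch two-sample t test
#'
#' The unequal-variance t test with Welch-Satterthwaite degrees of freedom.
#' When both samples are constant and equal the statistic is defined as 0
#' with p = 1 (no signal); constant but different samples give p = 0 with a
#' degenerate flag.
#'
#' @param a,b Numeric samples (length at least 2 each).
#' @return A `spot_test` with `detail$df`.
#' @export
welch_t <- function(a, b) {
  check_samples(a, b)
  w <- welch_stat(a, b)
  new_spot_test(w$t, w$p, "t.welch",
                detail = list(df = w$df, degenerate = w$degenerate))
}

#' Resampling configuration for permutation and bootstrap tests
#'
#' @param n_boot Bootstrap resamples (default 25, the customary choice with
#'   only six gels per group; note 25 resamples give a p-value resolution
#'   of 0.04 in the percentile/pivotal constructions).
#' @param n_perm Monte-Carlo permutations, the string `"exact"` to force
#'   full enumeration, or `NULL` (default) to enumerate whenever the number
#'   of group assignments is at most `exact_limit` and otherwise sample
#'   10000.
#' @param seed Integer seed for all resampling draws.
#' @param exact_limit Enumeration threshold (default 200000 assignments).
#' @return A list of class `"resampling_config"`.
#' @export
resampling_config <- function(n_boot = 25L, n_perm = NULL, seed = 1L,
                              exact_limit = 200000L) {
  if (!is_count(n_boot, 1L)) stop_validation("n_boot must be >= 1")
  if (!is.null(n_perm) && !identical(n_perm, "exact") && !is_count(n_perm, 1L)) {
    stop_validation("n_perm must be NULL, a positive count, or \"exact\"")
  }
  structure(list(n_boot = as.integer(n_boot), n_perm = n_perm,
                 seed = as.integer(seed), exact_limit = exact_limit),
            class = "resampling_config")
}

#' Permutation t test
#'
#' Permutes the group labels and recomputes the Welch statistic.  All
#' `choose(n_a + n_b, n_a)` assignments are enumerated when feasible (at
#' most `exact_limit`, or `n_perm = "exact"`); otherwise assignments are
#' sampled with the configured seed, with the observed assignment always
#' included.  The p-value is the fraction of assignments whose absolute
#' statistic reaches the observed one; since the observed assignment is
#' counted, p is never 0 and exact p-values are multiples of
#' 1/#assignments.
#'
#' @param a,b Numeric samples.
#' @param config A [resampling_config()].
#' @return A `spot_test` with `detail$n_resamples` and `detail$exact`.
#' @export
permutation_t <- function(a, b, config = resampling_config()) {
  check_samples(a, b)
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  n_assign <- choose(n, na)
  w_obs <- welch_stat(a, b)
  t_obs <- abs(w_obs$t)
  stat_for <- function(ii) {
    w <- welch_stat(pooled[ii], pooled[-ii])
    abs(w$t)
  }
  exact <- identical(config$n_perm, "exact") ||
    (is.null(config$n_perm) && n_assign <= config$exact_limit)
  if (exact) {
    combs <- combn(n, na)
    stats <- apply(combs, 2L, stat_for)
    n_used <- ncol(combs)
  } else {
    n_mc <- if (is.numeric(config$n_perm)) config$n_perm else 10000L
    stats <- withr::with_seed(config$seed, {
      c(t_obs, vapply(seq_len(n_mc - 1L),
                      function(r) stat_for(sample.int(n, na)), numeric(1)))
    })
    n_used <- n_mc
  }
  # ties: count statistics equal to the observed one (within fp jitter)
  p <- sum(stats >= t_obs - 1e-12 * max(1, t_obs)) / n_used
  new_spot_test(w_obs$t, p, "t.perm",
                detail = list(n_resamples = n_used, exact = exact))
}

#' Chebyshev-bound ("Chebby Checker") test
#'
#' A distribution-free test: applies the two-sided Chebyshev inequality to
#' the Welch statistic, giving the p-value bound `min(1, 1/t^2)`.  By
#' construction it is conservative --- the bound holds for any sampling
#' distribution with finite variance --- and always at least as large as
#' the Welch p-value once `|t|` exceeds ~1.6.
#'
#' @param a,b Numeric samples.
#' @return A `spot_test`.
#' @export
chebby_checker <- function(a, b) {
  check_samples(a, b)
  w <- welch_stat(a, b)
  p <- if (!is.finite(w$t)) 0 else if (w$t == 0) 1 else min(1, 1 / w$t^2)
  new_spot_test(w$t, p, "chebby", detail = list(degenerate = w$degenerate))
}

#' Bootstrap t tests by confidence-interval inversion
#'
#' Draws `n_boot` within-group resamples (with replacement) and forms the
#' bootstrap distribution of the mean difference `d* = mean(a*) - mean(b*)`.
#' Three p-value constructions invert the corresponding confidence
#' interval for the observed difference `d`:
#' \describe{
#'   \item{normal}{`p = 2 * (1 - pnorm(|d| / sd(d*)))` --- the normal
#'     approximation with bootstrap standard error.}
#'   \item{percentile}{`p = 2 * min(frac(d* <= 0), frac(d* >= 0))`, capped
#'     at 1 --- the smallest level at which the percentile interval
#'     excludes 0.}
#'   \item{pivotal}{`p = 2 * min(frac(d* >= 2d), frac(d* <= 2d))`, capped
#'     at 1 --- inversion of the basic (pivotal) interval.}
#' }
#' A degenerate bootstrap (`sd(d*) = 0`) under the normal variant yields
#' p = 1 when `d = 0` and p = 0 otherwise, flagged in the detail.
#'
#' @param a,b Numeric samples.
#' @param variant `"normal"`, `"percentile"`, or `"pivotal"`.
#' @param config A [resampling_config()]; `n_boot` and `seed` are used.
#' @return A `spot_test` whose statistic is the observed mean difference.
#' @export
bootstrap_t <- function(a, b, variant = c("normal", "percentile", "pivotal"),
                        config = resampling_config()) {
  check_samples(a, b)
  variant <- match.arg(variant)
  d_hat <- mean(a) - mean(b)
  d_star <- withr::with_seed(config$seed, {
    vapply(seq_len(config$n_boot), function(r) {
      mean(sample(a, replace = TRUE)) - mean(sample(b, replace = TRUE))
    }, numeric(1))
  })
  inv <- boot_p_from_ci(d_star, d_hat, variant)
  new_spot_test(d_hat, inv$p, paste0("boot.", variant),
                detail = list(n_boot = config$n_boot,
                              degenerate = inv$degenerate))
}

# confidence-interval inversion of a bootstrap mean-difference sample;
# kept separate from the resampling so the formulas are testable on a
# hand-made d* vector
boot_p_from_ci <- function(d_star, d_hat, variant) {
  degenerate <- FALSE
  p <- switch(variant,
    normal = {
      s <- sd(d_star)
      if (s == 0) {
        degenerate <- TRUE
        if (d_hat == 0) 1 else 0
      } else {
        2 * (1 - pnorm(abs(d_hat) / s))
      }
    },
    percentile = min(1, 2 * min(mean(d_star <= 0), mean(d_star >= 0))),
    pivotal = min(1, 2 * min(mean(d_star >= 2 * d_hat),
                             mean(d_star <= 2 * d_hat)))
  )
  list(p = p, degenerate = degenerate)
}

#' Statistical test registry
#'
#' Labels understood by [run_spot_test()] and [test_matrix()]:
#' `t.welch`, `t.perm`, `chebby`, `boot.normal`, `boot.percentile`,
#' `boot.pivotal`.
#'
#' @return Character vector of labels.
#' @export
test_labels <- function() {
  c("t.welch", "t.perm", "chebby", "boot.normal", "boot.percentile",
    "boot.pivotal")
}

#' Run one registered test on a pair of samples
#'
#' @param label A label from [test_labels()].
#' @param a,b Numeric samples.
#' @param config A [resampling_config()] (used by the resampling tests).
#' @return A `spot_test`.
#' @export
run_spot_test <- function(label, a, b, config = resampling_config()) {
  switch(label,
         t.welch = welch_t(a, b),
         t.perm = permutation_t(a, b, config),
         chebby = chebby_checker(a, b),
         boot.normal = bootstrap_t(a, b, "normal", config),
         boot.percentile = bootstrap_t(a, b, "percentile", config),
         boot.pivotal = bootstrap_t(a, b, "pivotal", config),
         stop_validation("unknown test '%s'; valid labels: %s", label,
                         paste(test_labels(), collapse = ", ")))
}

#' Apply a test to every spot of a complete matrix
#'
#' Runs the chosen test spot by spot, comparing the two design groups.
#' Resampling is seeded per spot as `config$seed + row index`, so a fixed
#' seed reproduces the whole table.  Per-spot failures are returned as
#' degenerate rows (statistic `NA`, p 1) rather than aborting the table.
#'
#' @param x A complete [spot_matrix()] (impute first).
#' @param test_label A label from [test_labels()].
#' @param config A [resampling_config()].
#' @return A `test_table` data frame: `spot_id`, `statistic`, `p_value`,
#'   `test_label`, `degenerate`.
#' @export
test_matrix <- function(x, test_label, config = resampling_config()) {
  stopifnot(inherits(x, "spot_matrix"))
  if (!test_label %in% test_labels()) {
    stop_validation("unknown test '%s'; valid labels: %s", test_label,
                    paste(test_labels(), collapse = ", "))
  }
  if (!is_complete(x)) {
    stop_validation("test_matrix needs a complete matrix; impute first")
  }
  cols <- group_columns(x$design)
  a_idx <- cols[[1L]]; b_idx <- cols[[2L]]
  n <- n_spots(x)
  stat <- numeric(n); pv <- numeric(n); degen <- logical(n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    res <- tryCatch(
      run_spot_test(test_label, x$values[i, a_idx], x$values[i, b_idx], cfg_i),
      error = function(e) new_spot_test(NA_real_, 1, test_label,
                                        detail = list(degenerate = TRUE,
                                                      error = conditionMessage(e))))
    stat[i] <- res$statistic
    pv[i] <- res$p_value
    degen[i] <- isTRUE(res$detail$degenerate)
  }
  structure(data.frame(spot_id = rownames(x$values), statistic = stat,
                       p_value = pv, test_label = test_label,
                       degenerate = degen, stringsAsFactors = FALSE),
            class = c("test_table", "data.frame"))
}
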