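# Regression-based ("least squares") imputation family.
#
# The spot-wise ("gene") estimator predicts a missing cell from the most
# correlated other spots via single regressions combined with correlation
# weights w = (r^2 / (1 - r^2 + eps))^2.  The array-wise estimator is the
# same construction with spots and gels transposed.  EM variants refine the
# corresponding least-squares fill by iterated Gaussian conditional
# expectation under an estimated covariance (over gels for the array
# variant, over spots for the spot variant).  Combined/adaptive variants
# mix the two base estimators.

#' Least-squares imputation configuration
#'
#' @param variant One of `"LS.G"`, `"EM.G"`, `"LS.A"`, `"EM.A"`, `"LS.C"`,
#'   `"LS.Ad"`: spot-wise ("gene") or array-wise regression, their
#'   EM-refined versions, and the combined / adaptive mixtures.
#' @param n_neighbors Number of most-correlated predictors per missing cell
#'   (default 10).
#' @param em_tol EM stopping rule: relative change of the imputed cells
#'   (as a vector, `||new - old|| / ||old||`) between iterations
#'   (default 1e-4).
#' @param em_max_iter Maximum EM iterations (default 100); 0 returns the
#'   least-squares initialization untouched.
#' @param ridge_eps Small positive regularizer, used both in the correlation
#'   weights and (scaled by the mean covariance diagonal) as a ridge on
#'   estimated covariance matrices (default 1e-6).
#' @param holdout_fraction For `"LS.C"`: fraction of observed cells held out
#'   to fit the global mixing proportion (default 0.05).
#' @param seed Seed for the `"LS.C"` hold-out draw (default 1).
#' @param p_fixed Optional fixed mixing proportion in `[0, 1]` (1 = pure
#'   spot-wise, 0 = pure array-wise) overriding the fitted/adaptive value.
#' @return A list of class `"ls_config"`.
#' @export
ls_config <- function(variant = c("LS.G", "EM.G", "LS.A", "EM.A", "LS.C", "LS.Ad"),
                      n_neighbors = 10L, em_tol = 1e-4, em_max_iter = 100L,
                      ridge_eps = 1e-6, holdout_fraction = 0.05, seed = 1L,
                      p_fixed = NULL) {
  variant <- match.arg(variant)
  if (!is_count(n_neighbors, 1L)) stop_validation("n_neighbors must be >= 1")
  if (!(em_tol > 0)) stop_validation("em_tol must be positive")
  if (!is_count(em_max_iter, 0L)) stop_validation("em_max_iter must be >= 0")
  if (!(ridge_eps > 0)) stop_validation("ridge_eps must be positive")
  if (!is.null(p_fixed) && !is_proportion(p_fixed)) {
    stop_validation("p_fixed must lie in [0, 1]")
  }
  structure(list(variant = variant, n_neighbors = as.integer(n_neighbors),
                 em_tol = em_tol, em_max_iter = as.integer(em_max_iter),
                 ridge_eps = ridge_eps, holdout_fraction = holdout_fraction,
                 seed = as.integer(seed), p_fixed = p_fixed),
            class = "ls_config")
}

# Core weighted-regression estimator.  V: rows are prediction targets,
# columns are samples.  Returns estimates and weight mass for every missing
# cell of V (NA estimate where only the row-mean fallback applies).
ls_core <- function(V, n_neighbors, ridge_eps, min_shared = 3L) {
  obs <- !is.na(V)
  M <- V
  M[!obs] <- 0
  W <- obs * 1
  n <- W %*% t(W)                 # shared sample counts
  Sy <- M %*% t(W)                # sum of target over shared samples
  Sx <- W %*% t(M)                # sum of predictor over shared samples
  Syy <- (M^2) %*% t(W)
  Sxx <- W %*% t(M^2)
  Sxy <- M %*% t(M)
  cov_n <- n * Sxy - Sy * Sx      # n^2 * cov-ish quantities
  varx_n <- n * Sxx - Sx^2
  vary_n <- n * Syy - Sy^2
  denom <- varx_n * vary_n
  r <- cov_n / sqrt(pmax(denom, 0))
  r[!is.finite(r)] <- NA_real_
  r[n < min_shared] <- NA_real_
  r[pmax(denom, 0) == 0] <- NA_real_
  diag(r) <- NA_real_
  r2 <- pmin(r^2, 1)
  wmat <- (r2 / (1 - r2 + ridge_eps))^2
  slope <- cov_n / varx_n
  intercept <- (Sy - slope * Sx) / n

  est <- matrix(NA_real_, nrow(V), ncol(V))
  mass <- matrix(0, nrow(V), ncol(V))
  miss <- which(!obs, arr.ind = TRUE)
  for (h in seq_len(nrow(miss))) {
    i <- miss[h, 1L]; j <- miss[h, 2L]
    cand <- which(obs[, j] & !is.na(r[i, ]) & is.finite(slope[i, ]))
    if (length(cand) == 0L) next
    sel <- cand[order(-abs(r[i, cand]))][seq_len(min(n_neighbors, length(cand)))]
    pred <- intercept[i, sel] + slope[i, sel] * V[sel, j]
    w <- wmat[i, sel]
    ok <- is.finite(pred) & is.finite(w) & w > 0
    if (!any(ok)) next
    est[i, j] <- sum(w[ok] * pred[ok]) / sum(w[ok])
    mass[i, j] <- sum(w[ok])
  }
  list(est = est, mass = mass)
}

# fill missing cells of `vals` from an estimate matrix, falling back to row
# means where no regression estimate exists
fill_from_estimates <- function(vals, est) {
  out <- vals
  rm_ <- rowMeans(vals, na.rm = TRUE)
  idx <- which(is.na(vals), arr.ind = TRUE)
  e <- est[idx]
  e[is.na(e)] <- rm_[idx[, 1L]][is.na(e)]
  out[idx] <- e
  out
}

#' Spot-wise least-squares imputation (LS.G)
#'
#' Predicts each missing cell from the `n_neighbors` spots most correlated
#' with the target spot (Pearson, over mutually observed gels), excluding
#' spots themselves missing at the target gel.  Each neighbour contributes
#' its single-regression prediction, combined with weights
#' `(r^2/(1 - r^2 + ridge_eps))^2`.  Cells with no usable neighbour fall
#' back to the row average.
#'
#' @param x A [spot_matrix()].
#' @param config An [ls_config()].
#' @return An `imputation_result` with `method_label` `"LSM.LS.G"`.
#' @export
impute_ls_gene <- function(x, config = ls_config("LS.G")) {
  check_imputable(x)
  core <- ls_core(x$values, config$n_neighbors, config$ridge_eps)
  new_imputation_result(x, fill_from_estimates(x$values, core$est), "LSM.LS.G")
}

#' Array-wise least-squares imputation (LS.A)
#'
#' The same estimator as [impute_ls_gene()] with the roles of spots and
#' gels transposed: a cell missing on gel *j* is predicted by regressing
#' gel *j* on the other gels over the spots observed in both.
#'
#' @inheritParams impute_ls_gene
#' @return An `imputation_result` with `method_label` `"LSM.LS.A"`.
#' @export
impute_ls_array <- function(x, config = ls_config("LS.A")) {
  check_imputable(x)
  core <- ls_core(t(x$values), config$n_neighbors, config$ridge_eps)
  new_imputation_result(x, fill_from_estimates(x$values, t(core$est)),
                        "LSM.LS.A")
}

# solve(A, b) with escalating ridge if A is numerically singular
ridge_solve <- function(A, b) {
  scale <- mean(diag(A))
  for (lam in c(0, 1e-8, 1e-5, 1e-2)) {
    out <- tryCatch(solve(A + diag(lam * scale, ncol(A)), b),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop_validation("covariance submatrix is singular beyond repair")
}

# Gaussian EM for missing data: records in rows, variables in columns.
# E-step fills each record's missing block with its conditional mean and
# accumulates the conditional covariance; the M-step covariance includes
# that mass (the textbook correction --- without it the covariance is
# understated and the regressions over-trusted).  Convergence is judged on
# the imputed cells as a vector, ||new - old|| / ||old||, which is robust
# to individual near-zero cells.
em_iterate <- function(X, miss_by_record, tol, max_iter, ridge_eps) {
  converged <- max_iter == 0L
  n <- nrow(X)
  p <- ncol(X)
  Cacc <- matrix(0, p, p)
  for (it in seq_len(max_iter)) {
    mu <- colMeans(X)
    S <- (cov(X) * (n - 1) + Cacc) / n
    S <- S + diag(ridge_eps * mean(diag(S)) + 1e-300, p)
    Cacc <- matrix(0, p, p)
    delta2 <- 0
    norm2 <- 0
    for (i in seq_along(miss_by_record)) {
      m <- miss_by_record[[i]]
      if (length(m) == 0L) next
      o <- setdiff(seq_len(p), m)
      K <- ridge_solve(S[o, o, drop = FALSE], S[o, m, drop = FALSE])
      new <- mu[m] + as.numeric(crossprod(K, X[i, o] - mu[o]))
      Cacc[m, m] <- Cacc[m, m] + S[m, m, drop = FALSE] -
        S[m, o, drop = FALSE] %*% K
      old <- X[i, m]
      delta2 <- delta2 + sum((new - old)^2)
      norm2 <- norm2 + sum(old^2)
      X[i, m] <- new
    }
    if (sqrt(delta2) <= tol * max(sqrt(norm2), .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  list(X = X, converged = converged)
}

#' EM-refined imputation (EM.G / EM.A)
#'
#' Starts from the matching least-squares fill ([impute_ls_array()] for
#' `"EM.A"`, [impute_ls_gene()] for `"EM.G"`) and iterates the Gaussian
#' missing-data EM: the E-step replaces each missing cell by its
#' conditional mean given the observed cells of its record under the
#' current mean vector and covariance matrix (taken over the EM dimension:
#' gels for `"EM.A"`, spots for `"EM.G"`), and the M-step re-estimates mean
#' and covariance from the completed matrix including the accumulated
#' conditional covariance of the imputed blocks.  Stops when the relative
#' change of the imputed-cell vector drops below `em_tol`; non-convergence
#' within
#' `em_max_iter` returns the current fill with `converged = FALSE`.
#' Covariances are ridge-regularized by `ridge_eps` times the mean diagonal.
#'
#' @param x A [spot_matrix()].
#' @param config An [ls_config()] with `variant` `"EM.A"` or `"EM.G"`.
#' @return An `imputation_result` with `method_label` `"LSM.EM.A"` or
#'   `"LSM.EM.G"` and a `converged` flag.
#' @export
impute_em <- function(x, config = ls_config("EM.A")) {
  check_imputable(x)
  if (!config$variant %in% c("EM.A", "EM.G")) {
    stop_validation("impute_em needs variant EM.A or EM.G, got %s", config$variant)
  }
  init <- if (config$variant == "EM.A") impute_ls_array(x, config)
          else impute_ls_gene(x, config)
  vals <- init$matrix$values
  miss <- is.na(x$values)
  if (config$variant == "EM.A") {
    # records = spots, variables = gels
    mbr <- lapply(seq_len(nrow(vals)), function(i) which(miss[i, ]))
    res <- em_iterate(vals, mbr, config$em_tol, config$em_max_iter,
                      config$ridge_eps)
    filled <- res$X
  } else {
    # records = gels, variables = spots
    mbr <- lapply(seq_len(ncol(vals)), function(j) which(miss[, j]))
    res <- em_iterate(t(vals), mbr, config$em_tol, config$em_max_iter,
                      config$ridge_eps)
    filled <- t(res$X)
  }
  if (!res$converged && config$em_max_iter > 0L) {
    warning(sprintf("EM (%s) did not converge within %d iterations",
                    config$variant, config$em_max_iter))
  }
  new_imputation_result(x, filled, paste0("LSM.", config$variant),
                        extra = list(converged = res$converged))
}

#' Combined and adaptive least-squares imputation (LS.C / LS.Ad)
#'
#' Mixes the spot-wise and array-wise estimates, `p * spotwise + (1 - p) *
#' arraywise`.  `"LS.C"` fits a single global `p` by least squares on a
#' seeded hold-out of `holdout_fraction` of the observed cells (too few
#' usable hold-out cells: `p = 0.5` with a warning).  `"LS.Ad"` sets `p`
#' per missing cell from the relative correlation-weight mass of the two
#' estimators.  `p_fixed` in the config forces either endpoint.
#'
#' @param x A [spot_matrix()].
#' @param config An [ls_config()] with `variant` `"LS.C"` or `"LS.Ad"`.
#' @return An `imputation_result`; for `"LS.C"` the fitted global
#'   proportion is attached as `p_global`.
#' @export
impute_ls_combined <- function(x, config = ls_config("LS.C")) {
  check_imputable(x)
  if (!config$variant %in% c("LS.C", "LS.Ad")) {
    stop_validation("impute_ls_combined needs variant LS.C or LS.Ad")
  }
  vals <- x$values
  g <- ls_core(vals, config$n_neighbors, config$ridge_eps)
  a_t <- ls_core(t(vals), config$n_neighbors, config$ridge_eps)
  est_g <- g$est; mass_g <- g$mass
  est_a <- t(a_t$est); mass_a <- t(a_t$mass)
  rm_ <- rowMeans(vals, na.rm = TRUE)
  miss_idx <- which(is.na(vals), arr.ind = TRUE)

  p_global <- NULL
  if (config$variant == "LS.C") {
    p_global <- config$p_fixed %||%
      fit_global_p(vals, config)
  }

  out <- vals
  for (h in seq_len(nrow(miss_idx))) {
    i <- miss_idx[h, 1L]; j <- miss_idx[h, 2L]
    eg <- est_g[i, j]; ea <- est_a[i, j]
    if (is.na(eg) && is.na(ea)) {
      out[i, j] <- rm_[i]
      next
    }
    if (is.na(eg)) { out[i, j] <- ea; next }
    if (is.na(ea)) { out[i, j] <- eg; next }
    p <- if (config$variant == "LS.C") {
      p_global
    } else if (!is.null(config$p_fixed)) {
      config$p_fixed
    } else if (mass_g[i, j] + mass_a[i, j] > 0) {
      mass_g[i, j] / (mass_g[i, j] + mass_a[i, j])
    } else 0.5
    out[i, j] <- p * eg + (1 - p) * ea
  }
  label <- paste0("LSM.", config$variant)
  extra <- if (config$variant == "LS.C") list(p_global = p_global) else list()
  new_imputation_result(x, out, label, extra = extra)
}

# fit the global mixing proportion for LS.C on a seeded secondary hold-out
fit_global_p <- function(vals, config) {
  obs_idx <- which(!is.na(vals))
  # only hold out cells from rows that keep >= 3 observed values
  row_obs <- rowSums(!is.na(vals))
  rc <- arrayInd(obs_idx, dim(vals))
  eligible <- obs_idx[row_obs[rc[, 1L]] >= 4L]
  n_hold <- round(config$holdout_fraction * length(obs_idx))
  if (n_hold < 3L || length(eligible) < n_hold) {
    warning("LS.C: hold-out infeasible; using p = 0.5")
    return(0.5)
  }
  hold <- withr::with_seed(config$seed, sample(eligible, n_hold))
  v2 <- vals
  truth <- v2[hold]
  v2[hold] <- NA_real_
  g <- ls_core(v2, config$n_neighbors, config$ridge_eps)
  a_t <- ls_core(t(v2), config$n_neighbors, config$ridge_eps)
  eg <- g$est[hold]
  ea <- t(a_t$est)[hold]
  rm2 <- rowMeans(v2, na.rm = TRUE)[arrayInd(hold, dim(v2))[, 1L]]
  eg[is.na(eg)] <- rm2[is.na(eg)]
  ea[is.na(ea)] <- rm2[is.na(ea)]
  num <- sum((eg - ea) * (truth - ea))
  den <- sum((eg - ea)^2)
  if (den <= 0) return(0.5)
  min(1, max(0, num / den))
}
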