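#' NIPALS imputation configuration
#'
#' @param n_components Number of principal components ("nPR") used for the
#'   low-rank reconstruction (default 5).
#' @param tol Convergence threshold on the relative change of the score
#'   vector within a component (default 1e-6).
#' @param max_iter Maximum inner iterations per component (default 500).
#' @return A list of class `"nipals_config"`.
#' @export
nipals_config <- function(n_components = 5L, tol = 1e-6, max_iter = 500L) {
  if (!is_count(n_components, 1L)) stop_validation("n_components must be >= 1")
  if (!(tol > 0)) stop_validation("tol must be positive")
  if (!is_count(max_iter, 1L)) stop_validation("max_iter must be >= 1")
  structure(list(n_components = as.integer(n_components), tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "nipals_config")
}

#' NIPALS principal-component imputation
#'
#' Runs the nonlinear iterative partial least squares PCA algorithm, which
#' tolerates missing entries by restricting every inner regression to
#' observed cells.  Gels are treated as samples and spots as variables;
#' each spot is centred by its observed mean.  Score vectors are
#' re-orthogonalized against earlier components during the iteration: with
#' missing cells the update operator is not exactly symmetric and later
#' components can otherwise diverge along incompletely deflated
#' directions.  After extracting
#' `n_components` score/loading pairs the missing cells are imputed from
#' the rank-`n_components` reconstruction plus the removed means.
#'
#' @param x A [spot_matrix()].
#' @param config A [nipals_config()].
#' @return An `imputation_result` with `method_label` `"NIPALS(n)"` and a
#'   `converged` flag (`FALSE` if any component hit `max_iter`).
#' @export
impute_nipals <- function(x, config = nipals_config()) {
  check_imputable(x)
  stopifnot(inherits(config, "nipals_config"))
  ncomp <- config$n_components
  if (ncomp > min(dim(x$values))) {
    stop_validation("n_components (%d) exceeds min(n_spots, n_gels) = %d",
                    ncomp, min(dim(x$values)))
  }
  X <- t(x$values)                       # gels x spots
  mu <- colMeans(X, na.rm = TRUE)
  Xc <- sweep(X, 2L, mu)
  obs <- !is.na(Xc) * 1
  R <- Xc
  R[is.na(R)] <- 0
  n <- nrow(R); p <- ncol(R)
  Th <- matrix(0, n, ncomp)
  Ph <- matrix(0, p, ncomp)
  converged <- TRUE
  for (h in seq_len(ncomp)) {
    j0 <- which.max(colSums(R^2))
    t_vec <- R[, j0]
    if (all(t_vec == 0)) t_vec <- R[, which.max(colSums(abs(R)))]
    comp_ok <- FALSE
    p_vec <- rep(0, p)
    for (it in seq_len(config$max_iter)) {
      # each inner regression uses only observed cells; its denominator is
      # floored at 10% of the full mass so a sample (or variable) that
      # misses most of the current loading mass is shrunk toward zero
      # rather than amplified --- unfloored denominators are the second
      # divergence channel of missing-data NIPALS
      den_p <- as.numeric(crossprod(t_vec^2, obs))
      p_vec <- as.numeric(crossprod(t_vec, R))
      p_vec <- p_vec / pmax(den_p, 0.1 * sum(t_vec^2))
      p_vec[!is.finite(p_vec)] <- 0
      nrm <- sqrt(sum(p_vec^2))
      if (nrm == 0) { comp_ok <- TRUE; t_vec <- rep(0, n); break }
      p_vec <- p_vec / nrm
      den_t <- as.numeric(obs %*% p_vec^2)
      t_new <- as.numeric(R %*% p_vec)
      t_new <- t_new / pmax(den_t, 0.1)
      if (h > 1L) {
        # re-orthogonalize against earlier scores: with missing cells the
        # update operator is not symmetric and later components can
        # otherwise drift back into (and blow up along) deflated
        # directions
        prev <- Th[, seq_len(h - 1L), drop = FALSE]
        ss <- colSums(prev^2)
        ok <- ss > 0
        if (any(ok)) {
          coef <- as.numeric(crossprod(prev[, ok, drop = FALSE], t_new)) / ss[ok]
          t_new <- t_new - as.numeric(prev[, ok, drop = FALSE] %*% coef)
        }
      }
      delta <- sqrt(sum((t_new - t_vec)^2)) /
        max(sqrt(sum(t_new^2)), .Machine$double.eps)
      t_vec <- t_new
      if (delta < config$tol) { comp_ok <- TRUE; break }
    }
    if (!comp_ok) converged <- FALSE
    Th[, h] <- t_vec
    Ph[, h] <- p_vec
    R <- R - (t_vec %*% t(p_vec)) * obs  # deflate observed cells only
  }
  recon <- sweep(Th %*% t(Ph), 2L, mu, "+")   # gels x spots
  filled <- x$values
  miss <- which(is.na(filled))
  filled[miss] <- t(recon)[miss]
  if (!converged) {
    warning(sprintf("NIPALS: at least one of %d components did not converge",
                    ncomp))
  }
  new_imputation_result(x, filled, sprintf("NIPALS(%d)", ncomp),
                        extra = list(converged = converged,
                                     scores = Th, loadings = Ph))
}

#' Imputation method registry
#'
#' Labels understood by [impute_spots()], matching the names under which
#' the methods are usually reported: `"RowAve"`, `"KNN(k)"` for integer k,
#' `"LSM.LS.G"`, `"LSM.EM.G"`, `"LSM.LS.A"`, `"LSM.EM.A"`, `"LSM.LS.C"`,
#' `"LSM.LS.Ad"`, and `"NIPALS(n)"` for integer n.
#'
#' @return Character vector of label templates.
#' @export
imputation_methods <- function() {
  c("RowAve", "KNN(k)", "LSM.LS.G", "LSM.EM.G", "LSM.LS.A", "LSM.EM.A",
    "LSM.LS.C", "LSM.LS.Ad", "NIPALS(n)")
}

#' Impute by method label
#'
#' Dispatches a registry label (see [imputation_methods()]) to the matching
#' imputation function, e.g. `"KNN(5)"` or `"LSM.EM.A"`.
#'
#' @param x A [spot_matrix()].
#' @param method Registry label.
#' @param ... Extra arguments forwarded to the underlying config
#'   constructor ([knn_config()], [ls_config()] or [nipals_config()]);
#'   arguments the constructor does not know are ignored, so e.g. a seed
#'   can be passed uniformly to any method.
#' @return An `imputation_result`.
#' @export
impute_spots <- function(x, method, ...) {
  stopifnot(is.character(method), length(method) == 1L)
  dots <- list(...)
  cfg_for <- function(ctor, fixed) {
    keep <- dots[names(dots) %in% setdiff(names(formals(ctor)), names(fixed))]
    do.call(ctor, c(fixed, keep))
  }
  if (method == "RowAve") return(impute_row_average(x))
  mk <- regmatches(method, regexec("^KNN\\((\\d+)\\)$", method))[[1L]]
  if (length(mk) == 2L) {
    return(impute_knn(x, cfg_for(knn_config, list(k = as.integer(mk[2L])))))
  }
  mn <- regmatches(method, regexec("^NIPALS\\((\\d+)\\)$", method))[[1L]]
  if (length(mn) == 2L) {
    return(impute_nipals(
      x, cfg_for(nipals_config, list(n_components = as.integer(mn[2L])))))
  }
  ml <- regmatches(method,
                   regexec("^LSM\\.(LS\\.G|EM\\.G|LS\\.A|EM\\.A|LS\\.C|LS\\.Ad)$",
                           method))[[1L]]
  if (length(ml) == 2L) {
    cfg <- cfg_for(ls_config, list(variant = ml[2L]))
    return(switch(substr(ml[2L], 1L, 2L),
                  EM = impute_em(x, cfg),
                  LS = if (ml[2L] %in% c("LS.C", "LS.Ad")) {
                    impute_ls_combined(x, cfg)
                  } else if (ml[2L] == "LS.G") {
                    impute_ls_gene(x, cfg)
                  } else {
                    impute_ls_array(x, cfg)
                  }))
  }
  stop_validation("unknown imputation method '%s'; valid labels: %s",
                  method, paste(imputation_methods(), collapse = ", "))
}
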