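# --- shared imputation machinery --------------------------------------------

new_imputation_result <- function(x_before, values_after, method_label,
                                  extra = list()) {
  miss <- is.na(x_before$values)
  if (anyNA(values_after)) {
    left <- which(is.na(values_after), arr.ind = TRUE)
    stop_validation("imputation left %d cell(s) missing (first: spot %s, gel %s)",
                    nrow(left), rownames(x_before$values)[left[1L, 1L]],
                    colnames(x_before$values)[left[1L, 2L]])
  }
  idx <- which(miss)
  rc <- arrayInd(idx, dim(miss))
  cells <- data.frame(
    spot_id = rownames(x_before$values)[rc[, 1L]],
    gel_id = colnames(x_before$values)[rc[, 2L]],
    value = values_after[idx],
    stringsAsFactors = FALSE
  )
  neg <- sum(cells$value < 0)
  out <- c(list(matrix = spot_matrix(values_after, x_before$design,
                                     allow_negative = TRUE),
                imputed_cells = cells,
                method_label = method_label,
                n_negative = neg),
           extra)
  class(out) <- "imputation_result"
  out
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("imputation_result [%s]: %d cells imputed", x$method_label,
              nrow(x$imputed_cells)))
  if (x$n_negative > 0) cat(sprintf(" (%d negative estimates)", x$n_negative))
  cat("\n")
  invisible(x)
}

check_imputable <- function(x) {
  stopifnot(inherits(x, "spot_matrix"))
  empty <- rowSums(!is.na(x$values)) == 0L
  if (any(empty)) {
    stop_validation("spot(s) with no observed value: %s",
                    paste(rownames(x$values)[empty], collapse = ", "))
  }
}

# --- row average -------------------------------------------------------------

#' Row-average imputation
#'
#' Replaces each missing cell by the mean of the observed cells of its spot.
#' The simplest baseline; it shrinks within-spot variance the most of all
#' methods here.
#'
#' @param x A [spot_matrix()]; every spot must have at least one observed
#'   cell.
#' @return An `imputation_result`: list with the completed `matrix`, the
#'   `imputed_cells` data frame (`spot_id`, `gel_id`, `value`), and
#'   `method_label`.
#' @export
impute_row_average <- function(x) {
  check_imputable(x)
  vals <- x$values
  rm_ <- rowMeans(vals, na.rm = TRUE)
  idx <- which(is.na(vals), arr.ind = TRUE)
  vals[idx] <- rm_[idx[, 1L]]
  new_imputation_result(x, vals, "RowAve")
}

# --- k nearest neighbours ----------------------------------------------------

#' KNN imputation configuration
#'
#' @param k Number of neighbouring spots to average (default 5).
#' @param metric `"euclidean"` (default; distances over mutually observed
#'   gels, rescaled by `sqrt(n_gels / n_shared)` so overlaps of different
#'   sizes are comparable) or `"pearson"` (distance `1 - r`).
#' @param weighting `"inverse_distance"` (default) or `"uniform"` neighbour
#'   averaging.  Under inverse-distance weighting an exact zero-distance
#'   neighbour short-circuits: its value is returned directly.
#' @return A list of class `"knn_config"`.
#' @export
knn_config <- function(k = 5L, metric = c("euclidean", "pearson"),
                       weighting = c("inverse_distance", "uniform")) {
  if (!is_count(k, 1L)) stop_validation("k must be a positive count")
  structure(list(k = as.integer(k), metric = match.arg(metric),
                 weighting = match.arg(weighting)),
            class = "knn_config")
}

# pairwise spot distances tolerating missing cells
spot_distances <- function(vals, metric) {
  if (metric == "pearson") {
    r <- suppressWarnings(cor(t(vals), use = "pairwise.complete.obs"))
    d <- 1 - r
  } else {
    obs <- !is.na(vals)
    M <- vals
    M[!obs] <- 0
    W <- obs * 1
    nsh <- W %*% t(W)
    cross <- M %*% t(M)
    sq <- (M^2) %*% t(W)
    d2 <- sq + t(sq) - 2 * cross
    d2[d2 < 0] <- 0 # numerical noise
    d <- sqrt(d2 * ncol(vals) / nsh) # NaN where no overlap
  }
  diag(d) <- NA_real_
  d
}

#' K-nearest-neighbour imputation
#'
#' For a spot missing at gel *j*, candidate neighbours are the spots
#' observed at gel *j*; the `k` nearest (by the configured metric over
#' mutually observed gels) contribute a weighted average of their values at
#' gel *j*.  Fewer than `k` candidates: all are used; no candidate at all:
#' the row average fills in and the fallback is counted in the result.
#'
#' @param x A [spot_matrix()].
#' @param config A [knn_config()].
#' @return An `imputation_result` with `method_label` `"KNN(k)"` and an
#'   `n_fallback` count.
#' @export
impute_knn <- function(x, config = knn_config()) {
  check_imputable(x)
  stopifnot(inherits(config, "knn_config"))
  if (config$k >= n_spots(x)) {
    stop_validation("k (%d) must be smaller than the number of spots (%d)",
                    config$k, n_spots(x))
  }
  vals <- x$values
  out <- vals
  obs <- !is.na(vals)
  D <- spot_distances(vals, config$metric)
  rm_ <- rowMeans(vals, na.rm = TRUE)
  n_fallback <- 0L
  miss <- which(!obs, arr.ind = TRUE)
  for (h in seq_len(nrow(miss))) {
    i <- miss[h, 1L]; j <- miss[h, 2L]
    cand <- which(obs[, j] & is.finite(D[i, ]))
    if (length(cand) == 0L) {
      out[i, j] <- rm_[i]
      n_fallback <- n_fallback + 1L
      next
    }
    dd <- D[i, cand]
    sel <- cand[order(dd)][seq_len(min(config$k, length(cand)))]
    dsel <- D[i, sel]
    v <- vals[sel, j]
    if (config$weighting == "uniform") {
      out[i, j] <- mean(v)
    } else if (any(dsel < 1e-12)) {
      out[i, j] <- mean(v[dsel < 1e-12])
    } else {
      w <- 1 / dsel
      out[i, j] <- sum(w * v) / sum(w)
    }
  }
  if (n_fallback > 0L) {
    warning(sprintf("KNN: %d cell(s) had no usable neighbour; row average used",
                    n_fallback))
  }
  new_imputation_result(x, out, sprintf("KNN(%d)", config$k),
                        extra = list(n_fallback = n_fallback))
}
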