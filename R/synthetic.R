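#' Configuration for the synthetic spot-matrix generator
#'
#' Describes a two-condition 2-DE experiment with log-normal spot abundances.
#' Defaults emulate a typical phospho-proteome screen: 70 matched spots on
#' 6 + 6 gels, 10 truly differential spots with a 1.5 log-unit shift,
#' between-spot abundance spread of 0.7 log units, a per-gel multiplicative
#' loading/staining effect, two latent covariation factors, and 20%
#' residual multiplicative noise.
#'
#' @param n_spots Number of protein spots (default 70).
#' @param n_per_group Gels per condition (default 6; at least 2).
#' @param de_fraction Fraction of spots truly differential (default 10/70).
#' @param effect_size Log-scale abundance shift added to differential spots
#'   in the second group (default 1.5).
#' @param log_mean,log_sd Mean and SD of per-spot baseline log-abundance
#'   (defaults 0 and 0.7; volumes are right-skewed log-normal).
#' @param gel_effect_sd Log-scale SD of the per-gel multiplicative effect
#'   (default 0.3), the loading/staining difference between gels; a
#'   column-constant factor that mean normalization removes.
#' @param n_factors,factor_sd Latent covariation structure: each spot gets
#'   standard-normal loadings on `n_factors` per-gel factors of SD
#'   `factor_sd` (defaults 2 and 0.18, log scale).  This emulates
#'   co-regulated protein groups --- the correlation among spots and among
#'   gels that neighbour- and covariance-based imputation exploits in real
#'   data --- and, unlike the gel effect, it survives mean normalization.
#' @param spot_noise_sd Log-scale SD of residual cell noise (default 0.2,
#'   i.e. roughly 20% CV).
#' @param seed Integer seed; one seed fully determines one dataset.
#' @param normalize Mean-normalize the generated matrix (default `TRUE`).
#' @param n_background Additional unmatched spots entering the
#'   normalization divisor only (default 330, so a 70-spot matrix is
#'   normalized over a 400-spot gel).  Gel images carry many more spots
#'   than the subset matched across all gels, and the total-volume divisor
#'   is computed from the whole gel; without this, the matched panel forms
#'   a closed composition and a handful of strong differential spots
#'   deflates every other spot in that group after normalization.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_spots = 70, n_per_group = 6,
                             de_fraction = 10 / 70, effect_size = 1.5,
                             log_mean = 0, log_sd = 0.7,
                             gel_effect_sd = 0.3, n_factors = 2L,
                             factor_sd = 0.18, spot_noise_sd = 0.2,
                             seed = 1L, normalize = TRUE,
                             n_background = 330L) {
  if (!is_count(n_spots, 1L)) stop_validation("n_spots must be a positive count")
  if (!is_count(n_per_group, 2L)) stop_validation("n_per_group must be >= 2")
  if (!is_proportion(de_fraction)) stop_validation("de_fraction must be in [0, 1]")
  if (!is_count(n_factors, 0L)) stop_validation("n_factors must be >= 0")
  if (!is_count(n_background, 0L)) stop_validation("n_background must be >= 0")
  for (nm in c("log_sd", "gel_effect_sd", "factor_sd", "spot_noise_sd")) {
    v <- get(nm)
    if (!(is.numeric(v) && length(v) == 1L && is.finite(v) && v >= 0)) {
      stop_validation("%s must be a non-negative number", nm)
    }
  }
  if (!is_count(seed, min = -.Machine$integer.max)) {
    stop_validation("seed must be an integer")
  }
  structure(list(n_spots = as.integer(n_spots),
                 n_per_group = as.integer(n_per_group),
                 de_fraction = de_fraction, effect_size = effect_size,
                 log_mean = log_mean, log_sd = log_sd,
                 gel_effect_sd = gel_effect_sd,
                 n_factors = as.integer(n_factors), factor_sd = factor_sd,
                 spot_noise_sd = spot_noise_sd,
                 seed = as.integer(seed), normalize = isTRUE(normalize),
                 n_background = as.integer(n_background)),
            class = "synthetic_config")
}

#' Generate a complete synthetic spot matrix with known truth
#'
#' Each cell is `exp(log_mean + spot effect + gel effect + latent factors +
#' group shift + noise)`, where the group shift of `±effect_size` applies
#' only to the differential spots in group B (up and down directions split
#' evenly, so normalization is not confounded by a one-sided change in
#' total volume) and the latent-factor term sums the spot's loadings times
#' the gel's factor scores (co-regulated protein groups).  The matrix is
#' strictly positive and, when `config$normalize` is `TRUE`, divided per
#' gel by the total volume of the whole simulated gel --- matched panel
#' plus `n_background` unmatched spots --- as the image software computes
#' it.  A fixed seed reproduces the dataset cell for cell.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `"synthetic_dataset"`: `matrix` (a complete
#'   [spot_matrix()]), `truth_de` (named logical, `TRUE` for truly
#'   differential spots), `truth_direction` (named -1/0/+1 giving each
#'   spot's shift direction), and `config`.
#' @export
generate_complete_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  ns <- config$n_spots
  m <- config$n_per_group
  gel_ids <- c(paste0("A", seq_len(m)), paste0("B", seq_len(m)))
  design <- group_design(gel_ids, rep(c("A", "B"), each = m))
  spot_ids <- sprintf("spot_%03d", seq_len(ns))

  out <- withr::with_seed(config$seed, {
    # the matched panel and the unmatched background spots share the
    # gel-level structure; the background enters the normalization
    # divisor only
    nt <- ns + config$n_background
    spot_eff <- rnorm(nt, 0, config$log_sd)
    gel_eff <- rnorm(2L * m, 0, config$gel_effect_sd)
    n_de <- round(config$de_fraction * ns)
    de <- rep(FALSE, ns)
    direction <- rep(0, nt)
    if (n_de > 0L) {
      which_de <- sample.int(ns, n_de)
      de[which_de] <- TRUE
      # balanced up/down shifts: an all-up panel would raise group B's
      # total volume and mean normalization would then turn every null
      # spot differential (compositional artifact)
      direction[which_de] <- sample(rep(c(-1, 1), length.out = n_de))
    }
    noise <- matrix(rnorm(nt * 2L * m, 0, config$spot_noise_sd), nt, 2L * m)
    shift <- outer(direction * config$effect_size,
                   as.integer(design$group == levels(design$group)[2L]))
    lv <- config$log_mean + spot_eff + noise + shift
    lv <- sweep(lv, 2L, gel_eff, "+")
    if (config$n_factors > 0L) {
      loadings <- matrix(rnorm(nt * config$n_factors), nt, config$n_factors)
      scores <- matrix(rnorm(2L * m * config$n_factors, 0, config$factor_sd),
                       2L * m, config$n_factors)
      lv <- lv + loadings %*% t(scores)
    }
    raw <- exp(lv)
    vals <- raw[seq_len(ns), , drop = FALSE]
    if (config$normalize) {
      vals <- sweep(vals, 2L, colSums(raw), "/")
    }
    list(values = vals, de = de, direction = direction[seq_len(ns)])
  })
  rownames(out$values) <- spot_ids
  sm <- spot_matrix(out$values, design, spot_ids = spot_ids)
  structure(list(matrix = sm,
                 truth_de = setNames(out$de, spot_ids),
                 truth_direction = setNames(out$direction, spot_ids),
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d spots x %d gels, %d truly differential\n",
              n_spots(x$matrix), n_gels(x$matrix), sum(x$truth_de)))
  invisible(x)
}

new_removal_record <- function(spot_id, gel_id, true_value, fraction, seed) {
  structure(data.frame(spot_id = spot_id, gel_id = gel_id,
                       true_value = true_value, stringsAsFactors = FALSE),
            fraction = fraction, seed = seed,
            class = c("removal_record", "data.frame"))
}

check_retention <- function(obs, design, constraint, min_per_group) {
  if (constraint == "per_group") {
    for (j in group_columns(design)) {
      if (any(rowSums(obs[, j, drop = FALSE]) < min_per_group)) return(FALSE)
    }
    TRUE
  } else {
    all(rowSums(obs) >= 1L)
  }
}

mask_cells <- function(x, idx) {
  vals <- x$values
  truth <- vals[idx]
  vals[idx] <- NA_real_
  rc <- arrayInd(idx, dim(x$values))
  list(matrix = spot_matrix(vals, x$design),
       spot_id = rownames(x$values)[rc[, 1L]],
       gel_id = colnames(x$values)[rc[, 2L]],
       truth = truth)
}

#' Mask cells completely at random
#'
#' Removes exactly `round(fraction * n_cells)` cells uniformly without
#' replacement from a complete matrix, recording their coordinates and true
#' values so imputation error can be scored.  Draws that would leave any
#' spot with fewer than `min_per_group` observed cells in either group are
#' rejected and redrawn (row averages and two-sample tests are undefined
#' otherwise); set `constraint = "overall"` for the weaker rule of at least
#' one observed cell per spot.
#'
#' @param x A complete [spot_matrix()].
#' @param fraction Proportion of cells to mask, in (0, 1).
#' @param seed Integer seed; the same seed reproduces the same mask.
#' @param constraint `"per_group"` (default) or `"overall"` retention rule.
#' @param min_per_group Minimum observed cells per spot per group under the
#'   per-group rule (default 2).
#' @param max_tries Redraw budget before giving up (default 10000).
#' @return List with `matrix` (the masked [spot_matrix()]) and `record`
#'   (a `removal_record` data frame: `spot_id`, `gel_id`, `true_value`,
#'   with `fraction` and `seed` attributes).
#' @export
remove_at_random <- function(x, fraction, seed,
                             constraint = c("per_group", "overall"),
                             min_per_group = 2L, max_tries = 10000L) {
  stopifnot(inherits(x, "spot_matrix"))
  constraint <- match.arg(constraint)
  if (!is_complete(x)) stop_validation("matrix must be complete before masking")
  if (!is_proportion(fraction, open_left = TRUE, open_right = TRUE)) {
    stop_validation("fraction must be strictly between 0 and 1")
  }
  nc <- length(x$values)
  n_remove <- round(fraction * nc)
  if (n_remove < 1L) stop_validation("fraction %.3g removes no cells", fraction)
  cols <- group_columns(x$design)
  if (constraint == "per_group") {
    max_removable <- sum(vapply(cols, function(j) {
      max(0L, length(j) - min_per_group)
    }, numeric(1))) * n_spots(x)
  } else {
    max_removable <- (n_gels(x) - 1L) * n_spots(x)
  }
  if (n_remove > max_removable) {
    stop_validation("cannot mask %d cells under the retention constraint (max %d)",
                    n_remove, max_removable)
  }
  idx <- draw_mcar_indices(x, n_remove, seed, constraint, min_per_group,
                           max_tries)
  idx <- sort(idx)
  mk <- mask_cells(x, idx)
  list(matrix = mk$matrix,
       record = new_removal_record(mk$spot_id, mk$gel_id, mk$truth,
                                   fraction, seed))
}

# seeded rejection sampling of a uniform cell subset honouring the
# retention constraint; returns the indices in draw order (a prefix of the
# draw is itself a uniform subset, used for nested-fraction masking)
draw_mcar_indices <- function(x, n_remove, seed, constraint, min_per_group,
                              max_tries) {
  nc <- length(x$values)
  idx <- withr::with_seed(seed, {
    for (i in seq_len(max_tries)) {
      cand <- sample.int(nc, n_remove)
      obs <- matrix(TRUE, nrow(x$values), ncol(x$values))
      obs[cand] <- FALSE
      if (check_retention(obs, x$design, constraint, min_per_group)) break
      cand <- NULL
    }
    cand
  })
  if (is.null(idx)) {
    stop_validation("no admissible mask found in %d tries (%d cells)",
                    max_tries, n_remove)
  }
  idx
}

#' Mask cells with intensity-dependent probability
#'
#' Emulates the observation that low-abundance spots go missing more often:
#' each cell of spot *i* is masked with probability proportional to
#' `plogis(-steepness * z_i)` where `z_i` is the z-score of the spot's mean
#' intensity, rescaled so the expected masked fraction equals
#' `target_fraction`.  `steepness = 0` reduces to masking completely at
#' random.  The same retention constraint as [remove_at_random()] applies.
#'
#' @param x A complete [spot_matrix()].
#' @param steepness Non-negative logistic slope on the intensity z-score
#'   (default 2).
#' @param target_fraction Expected overall masked fraction (default 0.25,
#'   matching the 20--30% missingness typical of 2-DE matrices).
#' @param seed Integer seed.
#' @inheritParams remove_at_random
#' @return As [remove_at_random()].
#' @export
remove_intensity_dependent <- function(x, steepness = 2, target_fraction = 0.25,
                                       seed,
                                       constraint = c("per_group", "overall"),
                                       min_per_group = 2L, max_tries = 10000L) {
  stopifnot(inherits(x, "spot_matrix"))
  constraint <- match.arg(constraint)
  if (!is_complete(x)) stop_validation("matrix must be complete before masking")
  if (!(is.numeric(steepness) && steepness >= 0)) {
    stop_validation("steepness must be non-negative")
  }
  if (!is_proportion(target_fraction, open_left = TRUE, open_right = TRUE)) {
    stop_validation("target_fraction must be strictly between 0 and 1")
  }
  m <- rowMeans(x$values)
  z <- if (sd(m) > 0) (m - mean(m)) / sd(m) else rep(0, length(m))
  base <- plogis(-steepness * z)
  p_spot <- pmin(base * target_fraction / mean(base), 0.99)
  p_cell <- matrix(p_spot, nrow(x$values), ncol(x$values))

  idx <- withr::with_seed(seed, {
    for (i in seq_len(max_tries)) {
      cand <- which(runif(length(p_cell)) < p_cell)
      if (length(cand) == 0L) next
      obs <- matrix(TRUE, nrow(x$values), ncol(x$values))
      obs[cand] <- FALSE
      if (check_retention(obs, x$design, constraint, min_per_group)) break
      cand <- NULL
    }
    cand
  })
  if (is.null(idx)) {
    stop_validation("no admissible mask found in %d tries", max_tries)
  }
  mk <- mask_cells(x, idx)
  list(matrix = mk$matrix,
       record = new_removal_record(mk$spot_id, mk$gel_id, mk$truth,
                                   length(idx) / length(x$values), seed))
}

#' Restore masked cells from a removal record
#'
#' Inverse of the masking operations; useful to verify that a record indeed
#' stores the pre-mask truth.
#'
#' @param x A masked [spot_matrix()].
#' @param record A `removal_record` from [remove_at_random()] or
#'   [remove_intensity_dependent()].
#' @return The restored [spot_matrix()].
#' @export
restore_removal <- function(x, record) {
  stopifnot(inherits(x, "spot_matrix"), inherits(record, "removal_record"))
  vals <- x$values
  ij <- cbind(match(record$spot_id, rownames(vals)),
              match(record$gel_id, colnames(vals)))
  if (anyNA(ij)) stop_validation("record refers to unknown spot/gel ids")
  vals[ij] <- record$true_value
  spot_matrix(vals, x$design)
}
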