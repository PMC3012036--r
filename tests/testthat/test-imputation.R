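# Imputation methods: exact-recovery limits, fallbacks, identities.

masked_copy <- function(m, cells) {
  v <- m$values
  v[cells] <- NA
  spot_matrix(v, m$design)
}

test_that("row average fills with the observed row mean", {
  v <- matrix(c(2, 4, NA, 6,
                5, NA, 5, 5,
                1, 1, 1, 1), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), NULL))
  m <- spot_matrix(v, design_2x2())
  r <- impute_row_average(m)
  expect_equal(unname(r$matrix$values[1, 3]), 4)
  expect_equal(unname(r$matrix$values[2, 2]), 5)
  expect_equal(nrow(r$imputed_cells), 2L)
  expect_identical(r$method_label, "RowAve")

  # complete input: identity, no imputed cells
  comp <- tiny_matrix()
  rc <- impute_row_average(comp)
  expect_equal(rc$matrix$values, comp$values)
  expect_equal(nrow(rc$imputed_cells), 0L)

  # all-missing row names the offending spot
  v[2, ] <- NA
  expect_error(impute_row_average(spot_matrix(v, design_2x2())), "s2")
})

test_that("KNN recovers a duplicated row exactly and falls back sanely", {
  v <- matrix(c(1, 2, 3, 4,
                1, 2, 3, NA,
                9, 9, 9, 9,
                4, 5, 6, 9), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), NULL))
  m <- spot_matrix(v, design_2x2())
  r <- impute_knn(m, knn_config(k = 1))
  # r1 matches r2 exactly on the shared gels: zero distance short-circuit
  expect_equal(unname(r$matrix$values[2, 4]), 4)
  expect_identical(r$method_label, "KNN(1)")

  # k = n_spots - 1 with uniform weighting equals the column mean over
  # spots observed at that gel
  r2 <- impute_knn(m, knn_config(k = 3, weighting = "uniform"))
  expect_equal(unname(r2$matrix$values[2, 4]), mean(c(4, 9, 9)))

  # k must stay below the number of spots
  expect_error(impute_knn(m, knn_config(k = 4)), "smaller than")
})

test_that("KNN observed cells are never modified and imputations stay in range", {
  ds <- default_dataset(seed = 2)
  rem <- remove_at_random(ds$matrix, 0.2, seed = 1)
  r <- impute_knn(rem$matrix, knn_config(k = 5))
  obs <- !is.na(rem$matrix$values)
  expect_equal(r$matrix$values[obs], rem$matrix$values[obs])
  rng <- range(rem$matrix$values, na.rm = TRUE)
  expect_true(all(r$imputed_cells$value >= rng[1] - 1e-12 &
                  r$imputed_cells$value <= rng[2] + 1e-12))
})

test_that("spot-wise LS recovers an exactly proportional neighbour", {
  # target = 2 x neighbour, plus unrelated noise rows
  set.seed(33)
  base <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  v <- rbind(2 * base, base,
             matrix(runif(4 * 12, 5, 6), 4, 12))
  rownames(v) <- paste0("s", 1:6)
  d <- design_6x6()
  m <- spot_matrix(v, d)
  mm <- masked_copy(m, cbind(1, 5))
  r <- impute_ls_gene(mm, ls_config("LS.G"))
  expect_lt(abs(r$matrix$values[1, 5] - 2 * base[5]), 1e-9)
  expect_identical(r$method_label, "LSM.LS.G")
})

test_that("array-wise LS recovers a proportional gel and matches the transposed spot-wise fit", {
  set.seed(34)
  v <- matrix(rlnorm(10 * 12), 10, 12, dimnames = list(paste0("s", 1:10), NULL))
  v[, 2] <- 2 * v[, 1]
  m <- spot_matrix(v, design_6x6())
  mm <- masked_copy(m, cbind(4, 2))
  r <- impute_ls_array(mm, ls_config("LS.A"))
  expect_lt(abs(r$matrix$values[4, 2] - 2 * v[4, 1]), 1e-9)

  # transpose symmetry: ls_array(M) == ls_gene(t(M)) cellwise
  set.seed(35)
  w <- matrix(rlnorm(10 * 8), 10, 8, dimnames = list(paste0("s", 1:10), NULL))
  d8 <- group_design(paste0("g", 1:8), rep(c("A", "B"), each = 4))
  d10 <- group_design(paste0("h", 1:10), rep(c("A", "B"), each = 5))
  holes <- cbind(c(1, 3, 7, 9), c(2, 5, 8, 4))
  wa <- w; wa[holes] <- NA
  m_a <- spot_matrix(wa, d8)
  m_g <- spot_matrix(t(wa), d10)
  cfg <- ls_config("LS.A", n_neighbors = 20)
  r_a <- impute_ls_array(m_a, cfg)
  r_g <- impute_ls_gene(m_g, ls_config("LS.G", n_neighbors = 20))
  expect_equal(unname(r_a$matrix$values), unname(t(r_g$matrix$values)),
               tolerance = 1e-10)
})

test_that("single-candidate LS equals the single regression prediction", {
  # two correlated rows, one unrelated constant-ish row excluded by
  # zero variance; only one usable neighbour remains
  x1 <- c(1, 2, 3, 4)
  v <- rbind(3 * x1 + 1, x1, rep(5, 4))
  rownames(v) <- paste0("s", 1:3)
  m <- spot_matrix(v, design_2x2())
  mm <- masked_copy(m, cbind(1, 3))
  r <- impute_ls_gene(mm, ls_config("LS.G"))
  # regression of s1 on s2 over gels 1, 2, 4 is exact: 3 * 3 + 1 = 10
  expect_lt(abs(r$matrix$values[1, 3] - 10), 1e-9)
})

test_that("EM refines its LS initialization and is exact on noiseless structure", {
  # em_max_iter = 0 returns the LS initialization untouched
  ds <- default_dataset(seed = 4)
  rem <- remove_at_random(ds$matrix, 0.15, seed = 2)
  init <- impute_ls_array(rem$matrix, ls_config("EM.A"))
  em0 <- impute_em(rem$matrix, ls_config("EM.A", em_max_iter = 0L))
  expect_equal(em0$matrix$values, init$matrix$values)

  # noiseless linear gel dependence is recovered by the conditional mean
  set.seed(36)
  v <- matrix(rlnorm(20 * 12), 20, 12, dimnames = list(paste0("s", 1:20), NULL))
  v[, 2] <- 2 * v[, 1]
  m <- spot_matrix(v, design_6x6())
  mm <- masked_copy(m, cbind(7, 2))
  r <- impute_em(mm, ls_config("EM.A"))
  expect_lt(abs(r$matrix$values[7, 2] - 2 * v[7, 1]) / (2 * v[7, 1]), 1e-4)
  expect_error(impute_em(mm, ls_config("LS.G")), "EM.A or EM.G")
})

test_that("EM.A beats row average on Gaussian data with strong gel covariance", {
  set.seed(37)
  d <- design_6x6()
  wins <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    L <- matrix(rnorm(12 * 2), 12, 2)
    Sg <- tcrossprod(L) + diag(0.4, 12)
    mu <- rnorm(12, 20, 1)
    X <- matrix(rnorm(50 * 12), 50, 12) %*% chol(Sg)
    X <- sweep(X, 2, mu, "+")
    X <- X - min(X) + 1
    rownames(X) <- sprintf("s%02d", 1:50)
    sm <- spot_matrix(X, d)
    rem <- remove_at_random(sm, 0.2, seed = 1000 + r)
    em <- suppressWarnings(impute_em(rem$matrix, ls_config("EM.A")))
    ra <- impute_row_average(rem$matrix)
    if (normalized_rmse(rem$record, em) < normalized_rmse(rem$record, ra)) {
      wins <- wins + 1L
    }
  }
  expect_gt(wins / n_rep, 0.9)
})

test_that("spot-wise LS gains nothing over row average when spots are independent noise", {
  # mirrors the small-matrix caveat: with uncorrelated spots the "nearest"
  # spots are spurious and LS.G cannot beat the row mean on average
  set.seed(38)
  d <- design_6x6()
  diff_sum <- 0
  n_rep <- 60L
  for (r in seq_len(n_rep)) {
    X <- matrix(rlnorm(40 * 12, sdlog = 0.3), 40, 12,
                dimnames = list(sprintf("s%02d", 1:40), NULL))
    sm <- spot_matrix(X, d)
    rem <- remove_at_random(sm, 0.1, seed = 2000 + r)
    g <- impute_ls_gene(rem$matrix, ls_config("LS.G"))
    ra <- impute_row_average(rem$matrix)
    diff_sum <- diff_sum +
      (normalized_rmse(rem$record, g) - normalized_rmse(rem$record, ra))
  }
  expect_gte(diff_sum / n_rep, 0)
})

test_that("combined LS endpoints reduce to the pure estimators", {
  ds <- default_dataset(seed = 6)
  rem <- remove_at_random(ds$matrix, 0.2, seed = 3)
  gene <- impute_ls_gene(rem$matrix, ls_config("LS.G"))
  arr <- impute_ls_array(rem$matrix, ls_config("LS.A"))
  p1 <- impute_ls_combined(rem$matrix, ls_config("LS.C", p_fixed = 1))
  p0 <- impute_ls_combined(rem$matrix, ls_config("LS.C", p_fixed = 0))
  expect_equal(p1$matrix$values, gene$matrix$values, tolerance = 1e-12)
  expect_equal(p0$matrix$values, arr$matrix$values, tolerance = 1e-12)
})

test_that("adaptive LS stays within the two base estimates cellwise", {
  ds <- default_dataset(seed = 6)
  rem <- remove_at_random(ds$matrix, 0.2, seed = 4)
  gene <- impute_ls_gene(rem$matrix, ls_config("LS.G"))
  arr <- impute_ls_array(rem$matrix, ls_config("LS.A"))
  ad <- impute_ls_combined(rem$matrix, ls_config("LS.Ad"))
  lo <- pmin(gene$imputed_cells$value, arr$imputed_cells$value)
  hi <- pmax(gene$imputed_cells$value, arr$imputed_cells$value)
  expect_true(all(ad$imputed_cells$value >= lo - 1e-9 &
                  ad$imputed_cells$value <= hi + 1e-9))
})

test_that("fitted global mixing proportion favours the structured side", {
  # data with only array structure: gels share a strong multiplicative
  # factor, spots are independent -> p should fall below 0.5 in most reps
  set.seed(39)
  d <- design_6x6()
  below <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    gel_factor <- exp(rnorm(12, 0, 0.6))
    X <- matrix(rlnorm(60 * 12, sdlog = 0.15), 60, 12) *
      matrix(gel_factor, 60, 12, byrow = TRUE)
    rownames(X) <- sprintf("s%02d", 1:60)
    sm <- spot_matrix(X, d)
    rem <- remove_at_random(sm, 0.15, seed = 3000 + r)
    fit <- impute_ls_combined(rem$matrix, ls_config("LS.C", seed = r))
    if (fit$p_global < 0.5) below <- below + 1L
  }
  expect_gt(below / n_rep, 0.9)
})

test_that("NIPALS completes exact low-rank structure and reconstructs complete data", {
  # rank-1 after centering: row i = mu_i + s_i * g_j, one missing cell.
  # NIPALS centres each spot by its *observed* mean, so the masked column's
  # score is set to the mean of the others to keep the centred form exactly
  # rank 1 with the cell masked.
  set.seed(40)
  g <- seq(-1.1, 1.1, length.out = 12)
  g[8] <- mean(g[-8])
  s <- runif(15, 0.5, 2)
  mu <- runif(15, 10, 20)
  v <- outer(s, g) + matrix(mu, 15, 12)
  rownames(v) <- sprintf("s%02d", 1:15)
  m <- spot_matrix(v, design_6x6())
  mm <- masked_copy(m, cbind(3, 8))
  r <- impute_nipals(mm, nipals_config(n_components = 1))
  expect_lt(abs(r$matrix$values[3, 8] - v[3, 8]), 1e-6)

  # full rank on a complete matrix: reconstruction is exact, nothing imputed
  ds <- default_dataset(seed = 8)
  full <- impute_nipals(ds$matrix,
                        nipals_config(n_components = min(dim(ds$matrix)),
                                      tol = 1e-10))
  expect_equal(nrow(full$imputed_cells), 0L)
  recon <- with(full, t(scores %*% t(loadings)) +
                  rowMeans(ds$matrix$values))
  expect_lt(max(abs(recon - ds$matrix$values)) / max(ds$matrix$values), 1e-8)

  expect_error(impute_nipals(mm, nipals_config(n_components = 13)), "exceeds")
})

test_that("all imputers are the identity on complete matrices and deterministic", {
  ds <- default_dataset(seed = 10)
  rem <- remove_at_random(ds$matrix, 0.2, seed = 9)
  labels <- c("RowAve", "KNN(5)", "LSM.LS.G", "LSM.EM.G", "LSM.LS.A",
              "LSM.EM.A", "LSM.LS.C", "LSM.LS.Ad", "NIPALS(5)")
  for (lab in labels) {
    r0 <- suppressWarnings(impute_spots(ds$matrix, lab))
    expect_equal(r0$matrix$values, ds$matrix$values,
                 tolerance = 1e-12, label = paste(lab, "identity"))
    r1 <- suppressWarnings(impute_spots(rem$matrix, lab))
    r2 <- suppressWarnings(impute_spots(rem$matrix, lab))
    expect_equal(r1$matrix$values, r2$matrix$values,
                 label = paste(lab, "determinism"))
    obs <- !is.na(rem$matrix$values)
    expect_equal(r1$matrix$values[obs], rem$matrix$values[obs],
                 label = paste(lab, "observed untouched"))
    expect_equal(nrow(r1$imputed_cells), sum(!obs))
  }
  expect_error(impute_spots(rem$matrix, "LSM.XX"), "unknown imputation method")
})
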