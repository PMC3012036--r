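# High-level drivers: the three-step analysis pipeline, the benchmark
# runner, and the synthetic-dataset writer.  All emit plain-text outputs
# plus a YAML manifest sufficient to reproduce the run byte for byte.

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), "NA", sprintf("%.10g", v))
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(path, fields) {
  fields$package_version <- as.character(packageVersion("gelimpute"))
  fields$r_version <- paste(R.version$major, R.version$minor, sep = ".")
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' Run the three-step analysis pipeline
#'
#' Majority-present filtering, imputation, per-spot testing, and
#' multiple-testing selection, in that order, writing the completed matrix,
#' the test table, the selection table, and a run manifest to `out_dir`.
#' With a fixed `seed` two invocations produce byte-identical outputs.
#'
#' @param input A [spot_matrix()] or the path of a spot-volume table.
#' @param design A [group_design()], a design-file path, or `NULL` when
#'   `input` is an object or carries an embedded design row.
#' @param method Imputation registry label (default `"LSM.EM.A"`).
#' @param test Test label (default `"t.welch"`).
#' @param procedure Selection procedure (default `"gfwer"`).
#' @param alpha Significance level (default 0.05).
#' @param k_allow gFWER allowance (default 1).
#' @param out_dir Output directory, created if absent.
#' @param seed Integer seed driving all resampling (default 1).
#' @param n_boot,n_perm Resampling sizes, see [resampling_config()].
#' @param filter Apply [filter_majority_present()] first (default `TRUE`).
#' @param missing_token,delimiter Parsing options for file input.
#' @return Invisibly, a list with the filtered/imputed matrix, the test
#'   table, the selection table, and the output paths.
#' @export
run_pipeline <- function(input, design = NULL, method = "LSM.EM.A",
                         test = "t.welch",
                         procedure = c("gfwer", "per_comparison", "bh_fdr"),
                         alpha = 0.05, k_allow = 1L, out_dir, seed = 1L,
                         n_boot = 25L, n_perm = NULL, filter = TRUE,
                         missing_token = "NA", delimiter = "\t") {
  procedure <- match.arg(procedure)
  t0 <- proc.time()[["elapsed"]]
  x <- if (inherits(input, "spot_matrix")) input else {
    read_spot_matrix(input, design = design, missing_token = missing_token,
                     delimiter = delimiter)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  timings <- c()
  step <- function(label, expr) {
    s <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[label]] <<- round(proc.time()[["elapsed"]] - s, 3)
    val
  }

  filtered <- if (filter) step("filter", filter_majority_present(x)) else x
  imputed <- if (is_complete(filtered)) {
    step("impute", impute_row_average(filtered)) # no-op on complete input
  } else {
    step("impute", impute_spots(filtered, method, seed = seed))
  }
  cfg <- resampling_config(n_boot = n_boot, n_perm = n_perm, seed = seed)
  tt <- step("test", test_matrix(imputed$matrix, test, cfg))
  sel_cfg <- selection_config(alpha = alpha, procedure = procedure,
                              k_allow = k_allow)
  sel <- step("select", selection_table(setNames(tt$p_value, tt$spot_id),
                                        sel_cfg))

  paths <- list(
    imputed_matrix = file.path(out_dir, "imputed_matrix.tsv"),
    tests = file.path(out_dir, "tests.tsv"),
    selection = file.path(out_dir, "selection.tsv"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  write_spot_matrix(imputed$matrix, paths$imputed_matrix,
                    missing_token = missing_token, delimiter = delimiter,
                    digits = 10)
  write_tsv(tt, paths$tests)
  write_tsv(sel, paths$selection)
  write_manifest(paths$manifest, list(
    step_order = c("filter_majority_present", "imputation", "testing",
                   "selection"),
    method = method, test = test, procedure = procedure,
    alpha = alpha, k_allow = as.integer(k_allow), seed = as.integer(seed),
    n_boot = as.integer(n_boot),
    n_spots_input = n_spots(x), n_spots_analyzed = n_spots(imputed$matrix),
    n_imputed_cells = nrow(imputed$imputed_cells),
    n_rejected = sum(sel$rejected),
    timings = as.list(timings),
    total_elapsed = round(proc.time()[["elapsed"]] - t0, 3)
  ))
  invisible(list(matrix = imputed$matrix, tests = tt, selection = sel,
                 paths = paths))
}

#' Write a synthetic dataset to disk
#'
#' Generates a complete matrix from a [synthetic_config()], writes it with
#' its truth table, and optionally also a masked version with its removal
#' record.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory, created if absent.
#' @param mask_fraction Optional fraction in (0, 1); when given, a masked
#'   matrix and removal record are written too.
#' @param mask_type `"mcar"` (default) or `"intensity"` masking.
#' @return Invisibly, the list of written paths.
#' @export
simulate_dataset <- function(config = synthetic_config(), out_dir,
                             mask_fraction = NULL,
                             mask_type = c("mcar", "intensity")) {
  mask_type <- match.arg(mask_type)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ds <- generate_complete_dataset(config)
  paths <- list(matrix = file.path(out_dir, "matrix.tsv"),
                truth = file.path(out_dir, "truth_de.tsv"))
  write_spot_matrix(ds$matrix, paths$matrix, digits = 10)
  write_tsv(data.frame(spot_id = names(ds$truth_de),
                       differential = unname(ds$truth_de)), paths$truth)
  if (!is.null(mask_fraction)) {
    rem <- if (mask_type == "mcar") {
      remove_at_random(ds$matrix, mask_fraction, seed = config$seed)
    } else {
      remove_intensity_dependent(ds$matrix, target_fraction = mask_fraction,
                                 seed = config$seed)
    }
    paths$masked <- file.path(out_dir, "masked.tsv")
    paths$removal <- file.path(out_dir, "removal.tsv")
    write_spot_matrix(rem$matrix, paths$masked, digits = 10)
    write_tsv(as.data.frame(rem$record), paths$removal)
  }
  paths$manifest <- file.path(out_dir, "manifest.yaml")
  write_manifest(paths$manifest, c(unclass(config),
                                   list(mask_fraction = mask_fraction,
                                        mask_type = if (!is.null(mask_fraction)) mask_type else NULL)))
  invisible(paths)
}

#' Run the benchmark experiments from a config
#'
#' Drives [run_rmse_experiment()] and/or [run_discovery_experiment()] on a
#' synthetic dataset, writing tidy TSV results (one row per method x
#' fraction x replicate, resp. per test x method x replicate), summary
#' tables, and optional figures.
#'
#' @param config Path of a YAML file, or an equivalent nested list, with
#'   optional blocks `dataset` (fields of [synthetic_config()]), `rmse`
#'   (`methods`, `fractions`, `n_reps`), `discovery` (`methods`, `tests`,
#'   `fraction`, `n_reps`, `alpha`), and a top-level `base_seed`.
#' @param out_dir Output directory, created if absent.
#' @param figures Also write PNG figures (default `FALSE`).
#' @return Invisibly, a list with the experiment objects and written paths.
#' @export
run_benchmarks <- function(config, out_dir, figures = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  base_seed <- config$base_seed %||% 1L
  ds_args <- config$dataset %||% list()
  ds_args$seed <- ds_args$seed %||% base_seed
  ds <- generate_complete_dataset(do.call(synthetic_config, ds_args))

  out <- list(paths = list())
  if (!is.null(config$rmse)) {
    rc <- config$rmse
    exp1 <- run_rmse_experiment(ds$matrix,
                                methods = unlist(rc$methods),
                                fractions = unlist(rc$fractions) %||%
                                  c(0.05, 0.10, 0.20),
                                n_reps = rc$n_reps %||% 100L,
                                base_seed = base_seed)
    out$rmse <- exp1
    out$paths$rmse_results <- file.path(out_dir, "rmse_results.tsv")
    out$paths$rmse_summary <- file.path(out_dir, "rmse_summary.tsv")
    write_tsv(exp1$results, out$paths$rmse_results)
    write_tsv(summary(exp1), out$paths$rmse_summary)
    if (figures) {
      grDevices::png(file.path(out_dir, "rmse_boxplot.png"), 900, 600)
      plot_rmse(exp1); grDevices::dev.off()
      grDevices::png(file.path(out_dir, "average_variance.png"), 900, 600)
      plot_average_variance(exp1); grDevices::dev.off()
    }
  }
  if (!is.null(config$discovery)) {
    dc <- config$discovery
    exp2 <- run_discovery_experiment(ds$matrix,
                                     methods = unlist(dc$methods),
                                     tests = unlist(dc$tests) %||% test_labels(),
                                     fraction = dc$fraction %||% 0.10,
                                     n_reps = dc$n_reps %||% 20L,
                                     alpha = dc$alpha %||% 0.05,
                                     base_seed = base_seed)
    out$discovery <- exp2
    out$paths$discovery_counts <- file.path(out_dir, "discovery_counts.tsv")
    out$paths$median_discoveries <- file.path(out_dir,
                                              "median_discoveries.tsv")
    write_tsv(exp2$counts, out$paths$discovery_counts)
    write_tsv(exp2$median_discoveries, out$paths$median_discoveries)
    cons <- do.call(rbind, lapply(names(exp2$consensus), function(tl) {
      do.call(rbind, lapply(names(exp2$consensus[[tl]]), function(m) {
        idx <- exp2$consensus[[tl]][[m]]
        if (length(idx) == 0L) return(NULL)
        data.frame(test = tl, method = m,
                   spot_id = rownames(ds$matrix$values)[idx],
                   stringsAsFactors = FALSE)
      }))
    }))
    out$paths$consensus <- file.path(out_dir, "consensus.tsv")
    write_tsv(cons %||% data.frame(test = character(), method = character(),
                                   spot_id = character()),
              out$paths$consensus)
    ov <- do.call(rbind, lapply(names(exp2$overlap), function(tl) {
      o <- exp2$overlap[[tl]]
      if (is.null(o)) return(NULL)
      data.frame(test = tl, region = names(o), count = unname(o),
                 stringsAsFactors = FALSE)
    }))
    out$paths$overlap <- file.path(out_dir, "overlap.tsv")
    write_tsv(ov %||% data.frame(test = character(), region = character(),
                                 count = integer()),
              out$paths$overlap)
    if (figures) {
      grDevices::png(file.path(out_dir, "median_discoveries.png"), 900, 600)
      plot_median_discoveries(exp2); grDevices::dev.off()
    }
  }
  out$paths$manifest <- file.path(out_dir, "manifest.yaml")
  write_manifest(out$paths$manifest, list(base_seed = base_seed,
                                          config = config))
  invisible(out)
}
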