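#' Spot-volume matrix with a two-group design
#'
#' The central container: a spots x gels numeric matrix of non-negative
#' normalized spot volumes, `NA` marking spots not observed on a gel,
#' together with the [group_design()] mapping gels to the two conditions.
#'
#' @param values Numeric matrix, rows = protein spots, columns = gels.
#'   All finite values must be non-negative; `NA` encodes a missing spot.
#' @param design A [group_design()]; its gels must match the columns.
#' @param spot_ids Optional character vector of unique spot identifiers;
#'   defaults to `rownames(values)` or `spot_1 ... spot_n`.
#' @param allow_negative Permit negative values.  Raw spot volumes are
#'   non-negative by construction, but regression-based imputation may
#'   extrapolate below zero; completed matrices set this flag rather than
#'   clip (clipping would bias error comparisons).
#' @return An object of class `"spot_matrix"`: a list with elements
#'   `values` (the dimnamed matrix) and `design`.
#' @export
spot_matrix <- function(values, design, spot_ids = NULL,
                        allow_negative = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_validation("values must be a numeric matrix")
  }
  if (!inherits(design, "group_design")) {
    stop_validation("design must be a group_design object")
  }
  if (ncol(values) != length(design$gel_ids)) {
    stop_validation("matrix has %d columns but design describes %d gels",
                    ncol(values), length(design$gel_ids))
  }
  if (is.null(spot_ids)) {
    spot_ids <- rownames(values) %||% sprintf("spot_%d", seq_len(nrow(values)))
  }
  spot_ids <- as.character(spot_ids)
  if (length(spot_ids) != nrow(values)) {
    stop_validation("spot_ids length does not match row count")
  }
  if (anyDuplicated(spot_ids)) {
    stop_validation("duplicate spot id: %s",
                    paste(unique(spot_ids[duplicated(spot_ids)]), collapse = ", "))
  }
  if (!allow_negative && any(values < 0, na.rm = TRUE)) {
    stop_validation("negative spot volumes are not allowed")
  }
  dimnames(values) <- list(spot_ids, design$gel_ids)
  structure(list(values = values, design = design), class = "spot_matrix")
}

#' @export
dim.spot_matrix <- function(x) dim(x$values)

#' @export
print.spot_matrix <- function(x, ...) {
  nm <- sum(is.na(x$values))
  cat(sprintf("spot_matrix: %d spots x %d gels, %d missing cells (%.1f%%)\n",
              nrow(x$values), ncol(x$values), nm,
              100 * nm / length(x$values)))
  print(x$design)
  invisible(x)
}

#' Number of spots / gels
#' @param x A [spot_matrix()].
#' @return Integer count.
#' @export
n_spots <- function(x) nrow(x$values)

#' @rdname n_spots
#' @export
n_gels <- function(x) ncol(x$values)

#' Is the matrix free of missing cells?
#' @param x A [spot_matrix()].
#' @return Logical scalar.
#' @export
is_complete <- function(x) !anyNA(x$values)

#' Coordinates of missing cells
#' @param x A [spot_matrix()].
#' @return Data frame with columns `spot_id`, `gel_id` (one row per missing
#'   cell, in column-major order).
#' @export
missing_cells <- function(x) {
  idx <- which(is.na(x$values), arr.ind = TRUE)
  data.frame(spot_id = rownames(x$values)[idx[, 1L]],
             gel_id = colnames(x$values)[idx[, 2L]],
             stringsAsFactors = FALSE)
}

#' Read a spot-volume table
#'
#' Parses a delimited spots x gels table.  The first row holds the gel ids,
#' the first column the spot ids.  The group design may be supplied as a
#' [group_design()] object, as a path to a two-column design file, or
#' embedded as a second header row (detected automatically when the first
#' data row is entirely non-numeric).
#'
#' Zeroes are kept as observed values: zero-substitution of missing spots is
#' exactly the practice this workflow replaces.  Pass `zero_as_missing =
#' TRUE` only if the upstream software is known to write zeros for
#' unmatched spots.
#'
#' @param path File to read.
#' @param design A [group_design()], a design-file path, or `NULL` if the
#'   file carries a design row.
#' @param missing_token Text marking a missing cell (default `"NA"`).
#' @param delimiter Field delimiter (default tab).
#' @param zero_as_missing Treat exact zeros as missing (default `FALSE`).
#' @param allow_negative Accept negative values, e.g. when reading back a
#'   written imputed matrix whose regression extrapolations went below
#'   zero (default `FALSE`).
#' @return A [spot_matrix()].
#' @export
read_spot_matrix <- function(path, design = NULL, missing_token = "NA",
                             delimiter = "\t", zero_as_missing = FALSE,
                             allow_negative = FALSE) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  if (file.size(path) == 0L) stop_validation("empty file: %s", path)
  raw <- tryCatch(
    read.table(path, sep = delimiter, header = FALSE, colClasses = "character",
               quote = "", comment.char = "", fill = FALSE,
               na.strings = character(0)),
    error = function(e) stop_validation("malformed table in %s: %s",
                                        path, conditionMessage(e)))
  if (nrow(raw) < 2L || ncol(raw) < 2L) {
    stop_validation("table in %s needs a header row plus at least one spot row", path)
  }
  gel_ids <- as.character(raw[1L, -1L])
  body <- raw[-1L, , drop = FALSE]

  parse_row <- function(cells) {
    out <- suppressWarnings(as.numeric(cells))
    out[cells == missing_token] <- NA_real_
    out
  }
  first <- parse_row(as.character(body[1L, -1L]))
  has_design_row <- all(is.na(first)) &&
    !any(as.character(body[1L, -1L]) == missing_token)
  if (has_design_row) {
    embedded <- group_design(gel_ids, as.character(body[1L, -1L]))
    body <- body[-1L, , drop = FALSE]
    if (is.null(design)) design <- embedded
  }
  if (is.null(design)) {
    stop_validation("no group design: supply one or embed a design row")
  }
  if (is.character(design)) design <- read_group_design(design, delimiter)
  if (nrow(body) == 0L) stop_validation("no spot rows in %s", path)

  spot_ids <- as.character(body[[1L]])
  cells <- as.matrix(body[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  vals[cells == missing_token] <- NA_real_
  bad <- is.na(vals) & cells != missing_token
  if (any(bad)) {
    stop_validation("non-numeric cell(s) not matching missing token '%s', e.g. '%s'",
                    missing_token, cells[which(bad)[1L]])
  }
  if (zero_as_missing) vals[vals == 0] <- NA_real_
  rownames(vals) <- spot_ids
  spot_matrix(vals, design, spot_ids = spot_ids,
              allow_negative = allow_negative)
}

#' Write a spot-volume table
#'
#' Values are written with a fixed number of significant digits (default 6),
#' so `read_spot_matrix(write_spot_matrix(x))` reproduces `x` up to that
#' precision.  With `design_row = TRUE` (the default) a second header row
#' carries the group labels, making the file self-contained.
#'
#' @param x A [spot_matrix()].
#' @param path Output file path.
#' @param missing_token Text written for missing cells (default `"NA"`).
#' @param delimiter Field delimiter (default tab).
#' @param digits Significant digits for volumes (default 6).
#' @param design_row Embed the group labels as a second header row.
#' @return `path`, invisibly.
#' @export
write_spot_matrix <- function(x, path, missing_token = "NA", delimiter = "\t",
                              digits = 6, design_row = TRUE) {
  stopifnot(inherits(x, "spot_matrix"))
  fmt <- function(v) {
    out <- sprintf(paste0("%.", digits, "g"), v)
    out[is.na(v)] <- missing_token
    out
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_validation("cannot write %s", path))
  on.exit(close(con))
  writeLines(paste(c("spot_id", colnames(x$values)), collapse = delimiter), con)
  if (design_row) {
    writeLines(paste(c("group", as.character(x$design$group)),
                     collapse = delimiter), con)
  }
  for (i in seq_len(nrow(x$values))) {
    writeLines(paste(c(rownames(x$values)[i], fmt(x$values[i, ])),
                     collapse = delimiter), con)
  }
  invisible(path)
}
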