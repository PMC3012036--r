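#' Two-group gel design
#'
#' Describes which gel (column) belongs to which of the two experimental
#' conditions, e.g. six control and six treated gels.  The first group label
#' encountered in `groups` becomes the first factor level; group ordering
#' only affects the sign of test statistics, never p-values.
#'
#' @param gel_ids Character vector of unique gel identifiers, in column order.
#' @param groups Vector (same length) assigning each gel to one of exactly two
#'   groups.  Each group must contain at least two gels.
#' @return An object of class `"group_design"` with fields `gel_ids` and
#'   `group` (a two-level factor).
#' @examples
#' group_design(c("c1", "c2", "t1", "t2"), c("ctrl", "ctrl", "trt", "trt"))
#' @export
group_design <- function(gel_ids, groups) {
  gel_ids <- as.character(gel_ids)
  groups <- as.character(groups)
  if (length(gel_ids) != length(groups)) {
    stop_validation("gel_ids (%d) and groups (%d) differ in length",
                    length(gel_ids), length(groups))
  }
  if (anyDuplicated(gel_ids)) {
    stop_validation("duplicate gel id: %s",
                    paste(unique(gel_ids[duplicated(gel_ids)]), collapse = ", "))
  }
  lv <- unique(groups)
  if (length(lv) != 2L) {
    stop_validation("design must have exactly two groups, found %d (%s)",
                    length(lv), paste(lv, collapse = ", "))
  }
  group <- factor(groups, levels = lv)
  if (any(table(group) < 2L)) {
    stop_validation("each group needs at least 2 gels")
  }
  structure(list(gel_ids = gel_ids, group = group), class = "group_design")
}

#' @export
print.group_design <- function(x, ...) {
  tab <- table(x$group)
  cat(sprintf("group_design: %d gels (%s)\n", length(x$gel_ids),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# column indices of each group, as a named list in level order
group_columns <- function(design) {
  split(seq_along(design$gel_ids), design$group)
}

#' Read a two-column gel design table
#'
#' Expects a delimited file with columns `gel_id` and `group`; a header line
#' is detected by its first field being `gel_id` or `gel` (case-insensitive).
#'
#' @param path File path.
#' @param delimiter Field delimiter, default tab.
#' @return A [group_design()] object.
#' @export
read_group_design <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop_validation("design file not found: %s", path)
  raw <- read.table(path, sep = delimiter, header = FALSE,
                    colClasses = "character", quote = "", comment.char = "",
                    na.strings = character(0))
  if (ncol(raw) < 2L) stop_validation("design file needs two columns (gel_id, group)")
  if (tolower(raw[1L, 1L]) %in% c("gel_id", "gel")) raw <- raw[-1L, , drop = FALSE]
  group_design(raw[[1L]], raw[[2L]])
}

#' Write a gel design table
#'
#' @param design A [group_design()] object.
#' @param path Output file path.
#' @param delimiter Field delimiter, default tab.
#' @return `path`, invisibly.
#' @export
write_group_design <- function(design, path, delimiter = "\t") {
  df <- data.frame(gel_id = design$gel_ids, group = as.character(design$group))
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}
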