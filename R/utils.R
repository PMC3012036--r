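# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_proportion <- function(x, open_left = FALSE, open_right = FALSE) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x))) return(FALSE)
  lo <- if (open_left) x > 0 else x >= 0
  hi <- if (open_right) x < 1 else x <= 1
  lo && hi
}

# sample variance per row with n-1 denominator; rows must be complete
row_variances <- function(values) {
  n <- ncol(values)
  m <- rowMeans(values)
  rowSums((values - m)^2) / (n - 1)
}
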