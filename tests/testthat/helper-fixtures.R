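# Small in-code fixtures shared across the suite.

design_2x2 <- function() {
  group_design(c("g1", "g2", "g3", "g4"), c("A", "A", "B", "B"))
}

design_6x6 <- function() {
  group_design(c(paste0("c", 1:6), paste0("t", 1:6)),
               rep(c("ctrl", "trt"), each = 6))
}

# deterministic small matrix; values strictly positive
tiny_matrix <- function(values = NULL, design = design_2x2(), ids = NULL) {
  if (is.null(values)) {
    values <- matrix(c(1, 2, 3, 4,
                       5, 6, 7, 8,
                       2, 4, 6, 8), nrow = 3, byrow = TRUE)
  }
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(values)))
  rownames(values) <- ids
  spot_matrix(values, design, spot_ids = ids)
}

default_dataset <- function(seed = 1L, ...) {
  generate_complete_dataset(synthetic_config(seed = seed, ...))
}
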