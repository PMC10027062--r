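# Internal helpers shared across the package.
#
# The canonical user-facing container is a "counts tibble": first column
# `probe_id` (character, unique), remaining columns one per sample
# (numeric, non-negative integers). These helpers validate that layout and
# convert to/from a plain probe x sample matrix for the numerics.

counts_tbl_to_matrix <- function(counts, arg = "counts") {
  if (!is.data.frame(counts) || ncol(counts) < 2L) {
    abort(sprintf("`%s` must be a data frame with a probe-id column and at least one sample column.", arg))
  }
  probe_ids <- as.character(counts[[1L]])
  sample_ids <- colnames(counts)[-1L]
  if (anyDuplicated(probe_ids)) {
    dup <- unique(probe_ids[duplicated(probe_ids)])
    abort(sprintf("Duplicated probe id(s): %s", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    abort(sprintf("Duplicated sample id(s): %s", paste(dup, collapse = ", ")))
  }
  m <- as.matrix(counts[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- sample_ids[!vapply(counts[-1L], is.numeric, logical(1))]
    abort(sprintf("Non-numeric counts in sample column(s): %s", paste(bad, collapse = ", ")))
  }
  if (anyNA(m)) abort("Counts contain missing values.")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    abort(sprintf("Negative count for probe '%s', sample '%s'.",
                  probe_ids[bad[[1L]]], sample_ids[bad[[2L]]]))
  }
  rownames(m) <- probe_ids
  m
}

# Integer coercion: instrument exports are read counts; accept numerics within
# 1e-9 of an integer, reject anything else naming the offending cell.
coerce_integer_counts <- function(m) {
  dev <- abs(m - round(m))
  if (any(dev > 1e-9)) {
    bad <- which(dev > 1e-9, arr.ind = TRUE)[1L, ]
    abort(sprintf("Non-integer count (%g) for probe '%s', sample '%s'.",
                  m[bad[[1L]], bad[[2L]]], rownames(m)[bad[[1L]]],
                  colnames(m)[bad[[2L]]]))
  }
  round(m)
}

matrix_to_counts_tbl <- function(m) {
  out <- as_tibble(as.data.frame(m, check.names = FALSE))
  dplyr::bind_cols(tibble(probe_id = rownames(m)), out)
}

library_sizes <- function(m) {
  ls <- colSums(m)
  if (any(ls <= 0)) {
    abort(sprintf("Zero library size for sample(s): %s",
                  paste(colnames(m)[ls <= 0], collapse = ", ")))
  }
  ls
}

qc_flag_levels <- c("PASS", "ALERT", "FAIL")

as_qc_flag <- function(x) factor(x, levels = qc_flag_levels)
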