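#' Tidy a QC run into one row per sample
#'
#' @param x A `panel_qc` object from [run_qc()].
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `library_size`, `pos_pct`,
#'   `neg_pct`, `neg_mean_cpm`, `delta`, `pos_flag`, `neg_flag`,
#'   `overall_flag`.
#' @method tidy panel_qc
#' @export
tidy.panel_qc <- function(x, ...) {
  x$samples
}

#' One-row summary of a QC run
#'
#' @param x A `panel_qc` object from [run_qc()].
#' @param ... Unused.
#' @return A one-row tibble: sample counts per flag, deviance SD and band
#'   limits (CPM), and whether the deviance sub-filter was applied.
#' @method glance panel_qc
#' @export
glance.panel_qc <- function(x, ...) {
  flags <- table(x$samples$overall_flag)
  tibble(
    n_samples = nrow(x$samples),
    n_pass = unname(flags[["PASS"]]),
    n_alert = unname(flags[["ALERT"]]),
    n_fail = unname(flags[["FAIL"]]),
    delta_sd = x$delta_sd,
    band_low = x$band_low,
    band_high = x$band_high,
    deviance_filter_applied = x$deviance_filter_applied
  )
}

#' Tidy PCA scores
#'
#' @param x A `panel_pca` object from [pca_samples()].
#' @param ... Unused.
#' @return A tibble: `sample_id`, one column per component (`PC1`, ...), plus
#'   any annotation columns attached by [join_annotation()].
#' @method tidy panel_pca
#' @export
tidy.panel_pca <- function(x, ...) {
  x$scores
}

#' Per-component PCA summary
#'
#' @param x A `panel_pca` object from [pca_samples()].
#' @param ... Unused.
#' @return A tibble: `component`, `explained_variance_ratio`,
#'   `cumulative_variance_ratio`, `n_genes_used`, `n_samples`.
#' @method glance panel_pca
#' @export
glance.panel_pca <- function(x, ...) {
  tibble(
    component = paste0("PC", seq_along(x$explained_variance_ratio)),
    explained_variance_ratio = x$explained_variance_ratio,
    cumulative_variance_ratio = cumsum(x$explained_variance_ratio),
    n_genes_used = x$n_genes_used,
    n_samples = nrow(x$scores)
  )
}

#' Tidy a heatmap export into long form
#'
#' @param x A `panel_heatmap` object from [hclust_orders()].
#' @param ... Unused.
#' @return A long tibble: `probe_id`, `sample_id`, z-scored `value`, with rows
#'   and columns in clustered leaf order.
#' @method tidy panel_heatmap
#' @export
tidy.panel_heatmap <- function(x, ...) {
  long <- tidyr::pivot_longer(matrix_to_counts_tbl(x$values), -"probe_id",
                              names_to = "sample_id", values_to = "value")
  dplyr::mutate(long,
                probe_id = factor(.data$probe_id, levels = x$row_order),
                sample_id = factor(.data$sample_id, levels = x$col_order))
}
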