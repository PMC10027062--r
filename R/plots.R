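#' Plot a QC run
#'
#' Two views of a `panel_qc` result, mirroring the two standard QC plots:
#'
#' * `type = "positive"`: per-sample percentage of reads allocated to the
#'   positive controls, with the ALERT and FAIL threshold lines.
#' * `type = "deviance"`: per-sample deviance of the mean negative-control CPM
#'   from the run average, with the `+/- k SD` band lines.
#'
#' @param object A `panel_qc` object from [run_qc()].
#' @param type `"positive"` or `"deviance"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot panel_qc
#' @export
autoplot.panel_qc <- function(object, type = c("positive", "deviance"), ...) {
  type <- match.arg(type)
  df <- object$samples
  df$sample_id <- factor(df$sample_id, levels = df$sample_id)
  flag_cols <- c(PASS = "#2b8a3e", ALERT = "#e8a902", FAIL = "#c92a2a")
  if (type == "positive") {
    thr <- object$thresholds
    ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$pos_pct,
                                     fill = .data$overall_flag)) +
      ggplot2::geom_col() +
      ggplot2::geom_hline(yintercept = thr$pos_fail, linetype = "dashed",
                          colour = flag_cols[["FAIL"]]) +
      ggplot2::geom_hline(yintercept = thr$pos_alert, linetype = "dashed",
                          colour = flag_cols[["ALERT"]]) +
      ggplot2::scale_fill_manual(values = flag_cols, drop = FALSE) +
      ggplot2::labs(x = NULL, y = "Positive-control reads (% of library)",
                    fill = "QC flag") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$delta,
                                     colour = .data$overall_flag)) +
      ggplot2::geom_point(size = 3) +
      ggplot2::geom_hline(yintercept = c(object$band_low, object$band_high),
                          linetype = "dashed") +
      ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
      ggplot2::scale_colour_manual(values = flag_cols, drop = FALSE) +
      ggplot2::labs(x = NULL, y = "Negative-control CPM deviance",
                    colour = "QC flag") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  }
}

#' Plot PCA sample scores
#'
#' @param object A `panel_pca` object from [pca_samples()].
#' @param colour Optional name of an annotation column (attached with
#'   [join_annotation()]) to colour points by.
#' @param ... Unused.
#' @return A ggplot object of PC1 vs PC2 (or PC1 alone for rank-1 results).
#' @method autoplot panel_pca
#' @export
autoplot.panel_pca <- function(object, colour = NULL, ...) {
  df <- object$scores
  evr <- object$explained_variance_ratio
  has_pc2 <- "PC2" %in% colnames(df)
  aes <- if (has_pc2) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  } else {
    ggplot2::aes(x = .data$PC1, y = 0)
  }
  p <- ggplot2::ggplot(df, aes) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * evr[[1L]]),
      y = if (has_pc2) sprintf("PC2 (%.1f%%)", 100 * evr[[2L]]) else NULL) +
    ggplot2::theme_minimal()
  if (!is.null(colour)) {
    if (!colour %in% colnames(df)) {
      abort(sprintf("No column '%s' in the PCA scores; join an annotation first.", colour))
    }
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), size = 3)
  } else {
    p + ggplot2::geom_point(size = 3)
  }
}

#' Plot a clustered heatmap
#'
#' Renders the z-scored matrix with rows and columns in clustered leaf order.
#'
#' @param object A `panel_heatmap` object from [hclust_orders()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot panel_heatmap
#' @export
autoplot.panel_heatmap <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$sample_id, y = .data$probe_id,
                               fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   axis.text.y = ggplot2::element_blank())
}
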