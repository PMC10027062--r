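#' Principal component analysis of samples
#'
#' Restricts to the `top_genes` most variable probes, centers each gene across
#' samples (no unit scaling), and computes sample scores by singular value
#' decomposition. The sign of each component is fixed so that its
#' largest-magnitude gene loading is positive, making results reproducible
#' across platforms.
#'
#' When a QC result is supplied, samples can be excluded by flag before the
#' decomposition: `exclude = "fail"` drops FAIL samples, `"fail+alert"` also
#' drops ALERT samples.
#'
#' @param norm Normalized values tibble (see [normalize_counts()]); any
#'   `probe_id + samples` tibble works.
#' @param qc Optional `panel_qc` result used for exclusion.
#' @param exclude `"none"`, `"fail"` or `"fail+alert"`.
#' @param top_genes Number of most-variable genes to use (default 500; capped
#'   at the number of probes).
#' @return A `panel_pca` object with elements `scores` (tibble, `sample_id` +
#'   `PC1..PCk`), `explained_variance_ratio`, `loadings`, `n_genes_used`.
#' @export
pca_samples <- function(norm, qc = NULL,
                        exclude = c("none", "fail", "fail+alert"),
                        top_genes = 500) {
  exclude <- match.arg(exclude)
  stopifnot(top_genes >= 2)
  m <- counts_tbl_to_matrix(norm, arg = "norm")
  keep_samples <- colnames(m)
  if (exclude != "none") {
    if (is.null(qc)) abort("Excluding flagged samples needs a `qc` result.")
    drop_levels <- if (exclude == "fail") "FAIL" else c("FAIL", "ALERT")
    dropped <- qc$samples$sample_id[qc$samples$overall_flag %in% drop_levels]
    keep_samples <- setdiff(keep_samples, dropped)
  }
  if (length(keep_samples) < 2L) {
    abort("Fewer than 2 samples left after exclusion; cannot run PCA.")
  }
  m <- m[, keep_samples, drop = FALSE]
  gene_var <- apply(m, 1L, var)
  k <- min(as.integer(top_genes), nrow(m))
  top <- order(gene_var, decreasing = TRUE)[seq_len(k)]
  top <- sort(top)  # keep input order among the selected genes
  x <- m[top, , drop = FALSE]
  centered <- x - rowMeans(x)            # center each gene across samples
  sv <- svd(t(centered))                 # samples are observations
  ncomp <- min(nrow(sv$u), ncol(sv$u), sum(sv$d > sv$d[1L] * 1e-12))
  ncomp <- max(ncomp, 1L)
  scores <- sv$u[, seq_len(ncomp), drop = FALSE] %*%
    diag(sv$d[seq_len(ncomp)], ncomp)
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  # deterministic sign: largest-|loading| gene of each component is positive
  for (j in seq_len(ncomp)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- sv$d^2
  scores_tbl <- as_tibble(as.data.frame(scores))
  colnames(scores_tbl) <- paste0("PC", seq_len(ncomp))
  scores_tbl <- dplyr::bind_cols(tibble(sample_id = keep_samples), scores_tbl)
  rownames(loadings) <- rownames(x)
  colnames(loadings) <- paste0("PC", seq_len(ncomp))
  structure(list(
    scores = scores_tbl,
    explained_variance_ratio = (ev / sum(ev))[seq_len(ncomp)],
    loadings = loadings,
    n_genes_used = k
  ), class = "panel_pca")
}

#' @export
print.panel_pca <- function(x, ...) {
  cat(sprintf("<panel_pca> %d samples x %d components (%d genes used)\n",
              nrow(x$scores), length(x$explained_variance_ratio),
              x$n_genes_used))
  cat("  explained variance: ",
      paste(sprintf("%.1f%%", 100 * head(x$explained_variance_ratio, 5L)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Hierarchical clustering orders for a heatmap
#'
#' Z-scores each probe row (mean 0, SD 1; constant rows are flagged and set
#' to all zeros), clusters rows and columns hierarchically, and returns the
#' leaf orders and merge trees for rendering. `stats::hclust` is deterministic
#' with ties broken by input order.
#'
#' @param norm Normalized values tibble (see [normalize_counts()]).
#' @param distance `"euclidean"` or `"correlation"` (`1 - Pearson r`).
#' @param linkage `"average"`, `"complete"` or `"ward"` (Ward.D2).
#' @return A `panel_heatmap` object: z-scored `values` matrix, `row_order`
#'   and `col_order` (probe / sample ids in leaf order), `row_merge` and
#'   `col_merge` (hclust merge matrices), `constant_rows`, and `annotations`
#'   (`NULL` until [join_annotation()]).
#' @export
hclust_orders <- function(norm, distance = c("euclidean", "correlation"),
                          linkage = c("average", "complete", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  m <- counts_tbl_to_matrix(norm, arg = "norm")
  if (nrow(m) < 2L || ncol(m) < 2L) abort("Need at least 2 probes and 2 samples.")
  sds <- apply(m, 1L, sd)
  constant <- sds == 0
  if (all(constant)) abort("All probe rows are constant; nothing to cluster.")
  z <- (m - rowMeans(m)) / ifelse(constant, 1, sds)
  z[constant, ] <- 0
  if (any(constant)) {
    warn(sprintf("%d constant probe row(s) set to zero: %s",
                 sum(constant),
                 paste(head(rownames(m)[constant], 5L), collapse = ", ")))
  }
  dist_fun <- function(x) {
    if (distance == "euclidean") dist(x) else stats::as.dist(1 - cor(t(x)))
  }
  method <- c(average = "average", complete = "complete", ward = "ward.D2")[[linkage]]
  hr <- hclust(dist_fun(z), method = method)
  hc <- hclust(dist_fun(t(z)), method = method)
  structure(list(
    values = z,
    row_order = rownames(m)[hr$order],
    col_order = colnames(m)[hc$order],
    row_merge = hr$merge,
    col_merge = hc$merge,
    constant_rows = rownames(m)[constant],
    annotations = NULL
  ), class = "panel_heatmap")
}

#' @export
print.panel_heatmap <- function(x, ...) {
  cat(sprintf("<panel_heatmap> %d probes x %d samples, z-scored and clustered\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Attach sample annotations to a PCA or heatmap result
#'
#' Joins label columns by sample id. Samples without a matching annotation row
#' get the explicit label `"unannotated"` in every label column and are
#' reported with a warning; mismatches are never fatal and annotation rows for
#' unknown samples are ignored (also with a warning).
#'
#' @param result A `panel_pca` or `panel_heatmap` object.
#' @param ann Annotation tibble from [read_annotation()] (first column
#'   `sample_id`).
#' @return The same object with label columns attached: on the PCA scores
#'   tibble, or as the heatmap `annotations` tibble aligned to `col_order`.
#' @export
join_annotation <- function(result, ann) {
  stopifnot(is.data.frame(ann))
  colnames(ann)[1L] <- "sample_id"
  ids <- if (inherits(result, "panel_pca")) {
    result$scores$sample_id
  } else if (inherits(result, "panel_heatmap")) {
    result$col_order
  } else {
    abort("`result` must be a panel_pca or panel_heatmap object.")
  }
  unmatched <- setdiff(ids, ann$sample_id)
  if (length(unmatched) > 0L) {
    warn(sprintf("%d sample(s) without annotation, labelled 'unannotated': %s",
                 length(unmatched), paste(unmatched, collapse = ", ")))
  }
  extra <- setdiff(ann$sample_id, ids)
  if (length(extra) > 0L) {
    warn(sprintf("%d annotation row(s) match no sample and are ignored: %s",
                 length(extra), paste(extra, collapse = ", ")))
  }
  labels <- dplyr::left_join(tibble(sample_id = ids), ann, by = "sample_id")
  labels <- dplyr::mutate(
    labels,
    dplyr::across(-"sample_id", ~ ifelse(is.na(.x), "unannotated", .x)))
  if (inherits(result, "panel_pca")) {
    result$scores <- dplyr::left_join(result$scores, labels, by = "sample_id")
  } else {
    result$annotations <- labels
  }
  result
}
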