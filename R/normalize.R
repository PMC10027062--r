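#' Normalize a counts matrix for visualisation
#'
#' Three methods:
#'
#' * `"cpm"` (default): counts per million, see [compute_cpm()].
#' * `"log2cpm"`: `log2(cpm + 1)`.
#' * `"vst"`: a closed-form variance stabilizer for negative-binomial counts
#'   with variance `mu + alpha * mu^2` and a single common dispersion `alpha`
#'   ([vst_transform()]); `alpha` is estimated from the data with
#'   [estimate_dispersion()] unless supplied. Counts are rescaled to the
#'   median library size before transformation so samples are comparable.
#'
#' Control probes are removed before normalization by default when a
#' `control_spec` is supplied: in a failed run they would dominate any
#' ordination. The QC filters themselves ([run_qc()]) always use the full
#' matrix.
#'
#' @param counts Counts tibble (see [read_counts()]).
#' @param method `"cpm"`, `"log2cpm"` or `"vst"`.
#' @param controls Optional [control_spec()] naming probes to drop.
#' @param remove_controls Drop the control probes before normalizing
#'   (default: yes, whenever `controls` is given).
#' @param dispersion Common NB dispersion for `method = "vst"`; estimated from
#'   the data when `NULL`.
#' @return A tibble (first column `probe_id`, one column per sample) with
#'   attributes `method`, `dispersion` (vst only) and `controls_removed`.
#' @export
normalize_counts <- function(counts, method = c("cpm", "log2cpm", "vst"),
                             controls = NULL,
                             remove_controls = !is.null(controls),
                             dispersion = NULL) {
  method <- match.arg(method)
  m <- counts_tbl_to_matrix(counts)
  if (isTRUE(remove_controls)) {
    if (is.null(controls)) abort("`remove_controls = TRUE` needs a `controls` spec.")
    controls <- validate_controls(controls, rownames(m))
    keep <- setdiff(rownames(m), c(controls$positive_ids, controls$negative_ids))
    if (length(keep) == 0L) abort("No non-control probes left to normalize.")
    m <- m[keep, , drop = FALSE]
  }
  values <- switch(method,
    cpm = cpm_matrix(m),
    log2cpm = log2(cpm_matrix(m) + 1),
    vst = {
      lib <- library_sizes(m)
      scaled <- sweep(m, 2L, median(lib) / lib, "*")
      if (is.null(dispersion)) dispersion <- estimate_dispersion_matrix(m)
      vst_transform(scaled, dispersion)
    })
  out <- matrix_to_counts_tbl(values)
  attr(out, "method") <- method
  attr(out, "dispersion") <- if (method == "vst") dispersion else NULL
  attr(out, "controls_removed") <- isTRUE(remove_controls)
  out
}

#' Estimate a common negative-binomial dispersion
#'
#' Method-of-moments estimate of the quadratic overdispersion `alpha` in
#' `Var(X) = mu + alpha * mu^2`. Counts are first rescaled to the median
#' library size; for each gene with positive mean `m` and non-zero variance
#' `s^2` across samples, the per-gene excess is
#' `alpha_g = max(0, (s^2 - m) / m^2)`, and the estimate is the median of the
#' `alpha_g`. Constant genes carry no dispersion information and are dropped.
#'
#' @param counts Counts tibble with at least 2 samples.
#' @return A single non-negative number.
#' @export
estimate_dispersion <- function(counts) {
  estimate_dispersion_matrix(counts_tbl_to_matrix(counts))
}

estimate_dispersion_matrix <- function(m) {
  if (ncol(m) < 2L) abort("Dispersion estimation needs at least 2 samples.")
  lib <- library_sizes(m)
  scaled <- sweep(m, 2L, median(lib) / lib, "*")
  mu <- rowMeans(scaled)
  s2 <- apply(scaled, 1L, var)
  keep <- mu > 0 & s2 > 0
  if (!any(keep)) abort("No gene with positive mean and variance: cannot estimate dispersion.")
  alpha_g <- pmax(0, (s2[keep] - mu[keep]) / mu[keep]^2)
  median(alpha_g)
}

#' Closed-form NB variance-stabilizing transform
#'
#' For counts with variance `mu + alpha * mu^2`, the transform
#' `g(x) = (2 / sqrt(alpha)) * asinh(sqrt(alpha * x))` has approximately
#' constant variance; at `alpha = 0` (Poisson) it reduces to its limit
#' `g(x) = 2 * sqrt(x)`. Strictly increasing in `x`, with `g(0) = 0`.
#'
#' @param x Non-negative count(s); vector or matrix.
#' @param alpha Common dispersion, `>= 0`.
#' @return Transformed values, same shape as `x`.
#' @export
vst_transform <- function(x, alpha) {
  stopifnot(is.numeric(x), is.numeric(alpha), length(alpha) == 1L, alpha >= 0)
  if (any(x < 0)) abort("vst_transform() needs non-negative counts.")
  if (alpha == 0) return(2 * sqrt(x))
  (2 / sqrt(alpha)) * asinh(sqrt(alpha * x))
}

#' Write a normalized matrix with its JSON sidecar
#'
#' Writes the values as a delimited table plus a `<path>.json` sidecar
#' recording the method, the dispersion (for vst) and whether controls were
#' removed.
#'
#' @param norm Result of [normalize_counts()].
#' @param path Output path for the table.
#' @return `path`, invisibly.
#' @export
write_normalized <- function(norm, path) {
  write_table(norm, path)
  meta <- list(method = attr(norm, "method") %||% "unknown",
               controls_removed = isTRUE(attr(norm, "controls_removed")))
  if (!is.null(attr(norm, "dispersion"))) meta$dispersion <- attr(norm, "dispersion")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
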