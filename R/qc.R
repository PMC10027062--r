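#' QC thresholds
#'
#' The four tunable constants of the flag scheme, with the published defaults:
#'
#' * `pos_fail`: a sample FAILs when the percentage of its reads allocated to
#'   the positive controls exceeds this (default 40).
#' * `pos_alert`: ALERT when the positive-control percentage exceeds this
#'   (default 10; good-quality samples sit in the 0-5% range).
#' * `neg_fail`: FAIL when the percentage of reads allocated to the negative
#'   controls exceeds this share of the library (default 10).
#' * `sd_mult`: half-width of the negative-control deviance band in standard
#'   deviations (default 2).
#'
#' All comparisons are strict ("exceeds"): a sample at exactly the FAIL
#' threshold is not failed.
#'
#' @param pos_fail,pos_alert Positive-control percentages in (0, 100].
#' @param neg_fail Negative-control percentage in (0, 100].
#' @param sd_mult Positive multiplier of the deviance standard deviation.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(pos_fail = 40, pos_alert = 10, neg_fail = 10,
                          sd_mult = 2) {
  stopifnot(is.numeric(pos_fail), is.numeric(pos_alert), is.numeric(neg_fail),
            is.numeric(sd_mult))
  if (!(pos_alert > 0 && pos_alert < pos_fail && pos_fail <= 100)) {
    abort("Need 0 < pos_alert < pos_fail <= 100.")
  }
  if (!(neg_fail > 0 && neg_fail <= 100)) abort("Need 0 < neg_fail <= 100.")
  if (!(sd_mult > 0)) abort("Need sd_mult > 0.")
  structure(list(pos_fail = pos_fail, pos_alert = pos_alert,
                 neg_fail = neg_fail, sd_mult = sd_mult),
            class = "qc_thresholds")
}

#' @export
print.qc_thresholds <- function(x, ...) {
  cat(sprintf(
    "<qc_thresholds> pos FAIL > %g%%, pos ALERT > %g%%, neg FAIL > %g%%, band = %g SD\n",
    x$pos_fail, x$pos_alert, x$neg_fail, x$sd_mult))
  invisible(x)
}

#' Counts per million
#'
#' Scales each sample's counts by its library size (the column total over ALL
#' probes, controls included) times one million, so every CPM column sums to
#' `1e6`.
#'
#' @param counts Counts tibble (see [read_counts()]).
#' @return A tibble of the same shape with CPM values.
#' @export
compute_cpm <- function(counts) {
  m <- counts_tbl_to_matrix(counts)
  matrix_to_counts_tbl(cpm_matrix(m))
}

cpm_matrix <- function(m) {
  sweep(m, 2L, library_sizes(m), "/") * 1e6
}

#' Percentage of a sample's reads allocated to a probe set
#'
#' @param counts Counts tibble.
#' @param control_ids Probe ids to sum over.
#' @param sample_id Sample to evaluate; `NULL` returns all samples.
#' @return A tibble with columns `sample_id` and `pct`.
#' @export
control_fraction <- function(counts, control_ids, sample_id = NULL) {
  m <- counts_tbl_to_matrix(counts)
  missing <- setdiff(control_ids, rownames(m))
  if (length(missing) > 0L) {
    abort(sprintf("Unknown control id(s): %s", paste(missing, collapse = ", ")))
  }
  if (!is.null(sample_id)) {
    unknown <- setdiff(sample_id, colnames(m))
    if (length(unknown) > 0L) {
      abort(sprintf("Unknown sample id(s): %s", paste(unknown, collapse = ", ")))
    }
    m <- m[, sample_id, drop = FALSE]
  }
  pct <- 100 * colSums(m[control_ids, , drop = FALSE]) / library_sizes(m)
  tibble(sample_id = colnames(m), pct = unname(pct))
}

#' Mean negative-control CPM per sample
#'
#' The arithmetic mean of a sample's CPM values over the negative-control
#' probes: the per-sample background level the deviance filter works on.
#'
#' @param cpm CPM tibble as returned by [compute_cpm()].
#' @param negative_ids Negative-control probe ids.
#' @return A tibble with columns `sample_id` and `neg_mean_cpm`.
#' @export
negative_mean_cpm <- function(cpm, negative_ids) {
  m <- counts_tbl_to_matrix(cpm)
  if (length(negative_ids) == 0L) abort("Empty negative-control set.")
  missing <- setdiff(negative_ids, rownames(m))
  if (length(missing) > 0L) {
    abort(sprintf("Unknown negative-control id(s): %s",
                  paste(missing, collapse = ", ")))
  }
  tibble(sample_id = colnames(m),
         neg_mean_cpm = unname(colMeans(m[negative_ids, , drop = FALSE])))
}

#' Deviance of each sample's negative-control CPM from the run average
#'
#' For samples `i = 1..N`, `delta_i = CPM_i - mean_j(CPM_j)`, where `CPM_i` is
#' the sample's mean negative-control CPM. The deviances sum to zero by
#' construction; samples outside `+/- sd_mult * SD(delta)` show
#' sample-specific background.
#'
#' @param neg_mean_cpm Numeric vector of per-sample mean negative-control CPM.
#' @return Numeric vector of deviances, same order and names.
#' @export
negative_deviance <- function(neg_mean_cpm) {
  if (length(neg_mean_cpm) == 0L) abort("Empty input: no samples.")
  neg_mean_cpm - mean(neg_mean_cpm)
}

#' Flag a sample on the positive-control filter
#'
#' FAIL when the positive-control percentage exceeds `pos_fail`, ALERT when it
#' exceeds `pos_alert`, PASS otherwise. Strict inequalities.
#'
#' @param pos_pct Percentage(s) of reads allocated to the positive controls.
#' @param thresholds A [qc_thresholds()].
#' @return A factor with levels PASS, ALERT, FAIL (vectorised over `pos_pct`).
#' @export
flag_positive <- function(pos_pct, thresholds = qc_thresholds()) {
  stopifnot(all(pos_pct >= 0 & pos_pct <= 100))
  as_qc_flag(ifelse(pos_pct > thresholds$pos_fail, "FAIL",
                    ifelse(pos_pct > thresholds$pos_alert, "ALERT", "PASS")))
}

#' Flag a sample on the negative-control filter
#'
#' Two sub-filters: FAIL when the negative-control percentage exceeds
#' `neg_fail` percent of the library; otherwise ALERT when the deviance filter
#' is applied and the deviance lies outside the `sd_mult * delta_sd` band
#' (two-sided on `|delta|` by default, or high-side only with
#' `band = "upper"`, since only elevated negative-control signal indicates
#' contamination); else PASS.
#'
#' @param neg_pct Percentage(s) of reads allocated to the negative controls.
#' @param delta Deviance(s) from [negative_deviance()].
#' @param delta_sd Standard deviation of the deviances across the run.
#' @param thresholds A [qc_thresholds()].
#' @param deviance_filter_applied Whether the band sub-filter is active
#'   (it is skipped for runs of fewer than 3 samples).
#' @param band `"two-sided"` or `"upper"`.
#' @return A factor with levels PASS, ALERT, FAIL.
#' @export
flag_negative <- function(neg_pct, delta, delta_sd,
                          thresholds = qc_thresholds(),
                          deviance_filter_applied = TRUE,
                          band = c("two-sided", "upper")) {
  band <- match.arg(band)
  stopifnot(delta_sd >= 0)
  dev_stat <- if (band == "two-sided") abs(delta) else delta
  outlier <- deviance_filter_applied & dev_stat > thresholds$sd_mult * delta_sd
  as_qc_flag(ifelse(neg_pct > thresholds$neg_fail, "FAIL",
                    ifelse(outlier, "ALERT", "PASS")))
}

#' Combine the two per-filter flags
#'
#' FAIL dominates ALERT dominates PASS: a sample is FAIL when either filter is
#' FAIL, else ALERT when either is ALERT, else PASS.
#'
#' @param pos_flag,neg_flag Flags (character or factor), vectorised.
#' @return A factor with levels PASS, ALERT, FAIL.
#' @export
combine_flags <- function(pos_flag, neg_flag) {
  p <- match(as.character(pos_flag), qc_flag_levels)
  n <- match(as.character(neg_flag), qc_flag_levels)
  if (anyNA(p) || anyNA(n)) abort("Flags must be PASS, ALERT or FAIL.")
  as_qc_flag(qc_flag_levels[pmax(p, n)])
}

#' Run the full sample quality control
#'
#' Computes, per sample: library size (over all probes, controls included),
#' positive- and negative-control read percentages, mean negative-control CPM,
#' its deviance from the run average, and the three flags. The deviance band
#' is `+/- sd_mult` sample standard deviations (denominator N-1) of the
#' deviances; with fewer than 3 samples the band is statistically meaningless
#' and the deviance sub-filter is skipped with a warning.
#'
#' @param counts Counts tibble (see [read_counts()]).
#' @param controls A [control_spec()]; defaults to prefix detection via
#'   [detect_controls()].
#' @param thresholds A [qc_thresholds()].
#' @param band Deviance band sidedness, see [flag_negative()].
#' @return A `panel_qc` object; see [tidy.panel_qc()], [glance.panel_qc()],
#'   [qc_pass_table()], [qc_flagged_table()], [autoplot.panel_qc()].
#' @examples
#' run <- simulate_run(scenario_config("single_pos_failure", seed = 1))
#' qc <- run_qc(run$counts)
#' glance(qc)
#' @export
run_qc <- function(counts, controls = detect_controls(counts),
                   thresholds = qc_thresholds(),
                   band = c("two-sided", "upper")) {
  band <- match.arg(band)
  m <- counts_tbl_to_matrix(counts)
  controls <- validate_controls(controls, rownames(m))
  if (length(controls$positive_ids) == 0L || length(controls$negative_ids) == 0L) {
    abort("QC needs at least one positive and one negative control probe.")
  }
  lib <- library_sizes(m)
  n <- ncol(m)
  pos_pct <- 100 * colSums(m[controls$positive_ids, , drop = FALSE]) / lib
  neg_pct <- 100 * colSums(m[controls$negative_ids, , drop = FALSE]) / lib
  cpm <- cpm_matrix(m)
  neg_mean <- colMeans(cpm[controls$negative_ids, , drop = FALSE])
  delta <- negative_deviance(neg_mean)
  deviance_filter_applied <- n >= 3L
  if (!deviance_filter_applied) {
    warn(sprintf(
      "Only %d sample(s): the deviance band needs at least 3, skipping the deviance sub-filter.", n))
  }
  delta_sd <- if (n >= 2L) sd(delta) else 0
  pos_flag <- flag_positive(pos_pct, thresholds)
  neg_flag <- flag_negative(neg_pct, delta, delta_sd, thresholds,
                            deviance_filter_applied, band)
  samples <- tibble(
    sample_id = colnames(m),
    library_size = unname(lib),
    pos_pct = unname(pos_pct),
    neg_pct = unname(neg_pct),
    neg_mean_cpm = unname(neg_mean),
    delta = unname(delta),
    pos_flag = pos_flag,
    neg_flag = neg_flag,
    overall_flag = combine_flags(pos_flag, neg_flag)
  )
  structure(list(
    samples = samples,
    delta_sd = delta_sd,
    band_low = -thresholds$sd_mult * delta_sd,
    band_high = thresholds$sd_mult * delta_sd,
    thresholds = thresholds,
    band = band,
    deviance_filter_applied = deviance_filter_applied,
    controls = controls
  ), class = "panel_qc")
}

#' @export
print.panel_qc <- function(x, ...) {
  counts <- table(x$samples$overall_flag)
  cat(sprintf("<panel_qc> %d samples: %d PASS, %d ALERT, %d FAIL\n",
              nrow(x$samples), counts[["PASS"]], counts[["ALERT"]],
              counts[["FAIL"]]))
  cat(sprintf("  deviance band: [%.4g, %.4g] CPM (SD %.4g, %s%s)\n",
              x$band_low, x$band_high, x$delta_sd, x$band,
              if (x$deviance_filter_applied) "" else ", not applied"))
  print(x$thresholds)
  invisible(x)
}

#' Samples passing QC
#'
#' @param qc A `panel_qc` object.
#' @return Tibble of samples with overall flag PASS, all QC columns included.
#' @export
qc_pass_table <- function(qc) {
  stopifnot(inherits(qc, "panel_qc"))
  dplyr::filter(qc$samples, .data$overall_flag == "PASS")
}

#' Samples flagged ALERT or FAIL
#'
#' @param qc A `panel_qc` object.
#' @return Tibble of samples with overall flag ALERT or FAIL.
#' @export
qc_flagged_table <- function(qc) {
  stopifnot(inherits(qc, "panel_qc"))
  dplyr::filter(qc$samples, .data$overall_flag != "PASS")
}
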