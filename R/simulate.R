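#' Configuration for a synthetic panel run
#'
#' Describes an instrument-like run with known ground truth: per-sample
#' library sizes (lognormal jitter around a mean), exact read budgets for the
#' positive (spike-in) and negative (non-human) control probes, and
#' negative-binomial counts for the panel genes.
#'
#' @param n_samples Number of samples.
#' @param n_genes Number of non-control probes.
#' @param n_pos,n_neg Number of positive / negative control probes
#'   (`POS1..`, `ANT1..`).
#' @param library_size Mean library size in reads.
#' @param library_log_sd SD of the lognormal library-size jitter (log scale).
#' @param dispersion Common NB dispersion of the gene counts.
#' @param pos_fraction,neg_fraction Per-sample fraction of reads allocated to
#'   the positive / negative controls; length 1 or `n_samples`.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @param scenario Optional label recording which preset built the config.
#' @return A `sim_config` object.
#' @seealso [scenario_config()] for the named presets, [simulate_run()].
#' @export
sim_config <- function(n_samples = 16, n_genes = 100, n_pos = 4, n_neg = 4,
                       library_size = 1e6, library_log_sd = 0.2,
                       dispersion = 0.3,
                       pos_fraction = 0.02, neg_fraction = 0.005,
                       seed = 1, scenario = "custom") {
  pos_fraction <- rep_len(pos_fraction, n_samples)
  neg_fraction <- rep_len(neg_fraction, n_samples)
  if (any(pos_fraction < 0) || any(neg_fraction < 0) ||
      any(pos_fraction + neg_fraction >= 1)) {
    abort("Need 0 <= pos_fraction, neg_fraction and pos_fraction + neg_fraction < 1 per sample.")
  }
  stopifnot(n_samples >= 1, n_genes >= 1, n_pos >= 1, n_neg >= 1,
            library_size > 0, dispersion >= 0)
  structure(list(n_samples = n_samples, n_genes = n_genes, n_pos = n_pos,
                 n_neg = n_neg, library_size = library_size,
                 library_log_sd = library_log_sd, dispersion = dispersion,
                 pos_fraction = pos_fraction, neg_fraction = neg_fraction,
                 seed = as.integer(seed), scenario = scenario),
            class = "sim_config")
}

#' Named scenario presets
#'
#' * `clean_run`: every sample in the good-quality regime (positive-control
#'   fractions 0.5-4%, negative 0.1-0.8%); all flags PASS.
#' * `single_pos_failure`: one sample with 50% of reads in the spike-ins
#'   (above the 40% FAIL threshold), the rest clean.
#' * `single_neg_contamination`: one sample with 15% of reads in the negative
#'   controls (above the 10% FAIL fraction), the rest clean.
#' * `alert_only`: one sample with 15% spike-in reads — inside the ALERT band
#'   (above 10%, below 40%) — none failing.
#' * `complete_run_failure`: every sample contaminated alike (negative
#'   fractions 18-22%): all samples exceed the 10% fraction rule, yet no
#'   deviance is outside the band because the whole run is shifted together.
#'
#' @param scenario Preset name.
#' @param n_samples Number of samples (default 16).
#' @param seed Integer seed.
#' @param ... Further arguments passed to [sim_config()].
#' @return A `sim_config`.
#' @export
scenario_config <- function(scenario = c("clean_run", "single_pos_failure",
                                         "single_neg_contamination",
                                         "alert_only", "complete_run_failure"),
                            n_samples = 16, seed = 1, ...) {
  scenario <- match.arg(scenario)
  # fraction jitter is drawn deterministically from the seed so the config
  # itself (not only the run) is reproducible
  fr <- withr::with_seed(as.integer(seed) + 1000L, list(
    pos = runif(n_samples, 0.005, 0.04),
    neg = runif(n_samples, 0.001, 0.008),
    neg_high = runif(n_samples, 0.18, 0.22)
  ))
  pos <- fr$pos
  neg <- fr$neg
  if (scenario == "single_pos_failure") pos[1L] <- 0.50
  if (scenario == "single_neg_contamination") neg[1L] <- 0.15
  if (scenario == "alert_only") pos[1L] <- 0.15
  if (scenario == "complete_run_failure") neg <- fr$neg_high
  sim_config(n_samples = n_samples, pos_fraction = pos, neg_fraction = neg,
             seed = seed, scenario = scenario, ...)
}

#' Generate a synthetic run with known ground truth
#'
#' Per sample: draws a library size, allocates the configured exact read
#' budgets to the control probes (multinomially within each control set, so
#' the realized control fractions equal the configured ones up to rounding),
#' and distributes the remaining reads over the panel genes by a multinomial
#' whose weights are negative-binomial draws around a fixed lognormal
#' gene-abundance profile — giving realistic overdispersion for the VST and
#' PCA while keeping the flag ground truth exact.
#'
#' Truth flags are computed from the generating fractions with the default
#' thresholds ([qc_thresholds()]); the deviance sub-filter is not part of the
#' truth (it depends on the realized run, not on a single sample's
#' parameters).
#'
#' @param config A [sim_config()] or [scenario_config()].
#' @return A list: `counts` (tibble as from [read_counts()]), `truth`
#'   (tibble: `sample_id`, `pos_flag`, `neg_flag`, `overall_flag` from the
#'   generating fractions), and `config`.
#' @export
simulate_run <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_samples
    pos_ids <- paste0("POS", seq_len(config$n_pos))
    neg_ids <- paste0("ANT", seq_len(config$n_neg))
    gene_ids <- sprintf("GENE%03d", seq_len(config$n_genes))
    # fixed relative abundance profile shared by all samples
    abundance <- rlnorm(config$n_genes, meanlog = 0, sdlog = 1.5)
    lib <- round(rlnorm(n, meanlog = log(config$library_size) -
                          config$library_log_sd^2 / 2,
                        sdlog = config$library_log_sd))
    lib <- pmax(lib, 1)
    counts <- matrix(0L, nrow = config$n_pos + config$n_neg + config$n_genes,
                     ncol = n,
                     dimnames = list(c(pos_ids, neg_ids, gene_ids),
                                     paste0("S", seq_len(n))))
    size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
    for (s in seq_len(n)) {
      pos_budget <- round(config$pos_fraction[s] * lib[s])
      neg_budget <- round(config$neg_fraction[s] * lib[s])
      gene_budget <- lib[s] - pos_budget - neg_budget
      counts[pos_ids, s] <- rmultinom(1L, pos_budget, rep(1, config$n_pos))
      counts[neg_ids, s] <- rmultinom(1L, neg_budget, rep(1, config$n_neg))
      mu <- abundance / sum(abundance) * gene_budget
      w <- if (is.finite(size)) rnbinom(config$n_genes, mu = mu, size = size)
           else stats::rpois(config$n_genes, mu)
      if (sum(w) == 0) w <- abundance
      counts[gene_ids, s] <- rmultinom(1L, gene_budget, w)
    }
    thr <- qc_thresholds()
    pos_flag <- flag_positive(100 * config$pos_fraction, thr)
    neg_flag <- as_qc_flag(ifelse(100 * config$neg_fraction > thr$neg_fail,
                                  "FAIL", "PASS"))
    list(
      counts = matrix_to_counts_tbl(counts),
      truth = tibble(sample_id = colnames(counts),
                     pos_flag = pos_flag,
                     neg_flag = neg_flag,
                     overall_flag = combine_flags(pos_flag, neg_flag)),
      config = config
    )
  })
}

#' Write a simulated run to disk as fixture files
#'
#' Writes the counts in both supported dialects (plain delimited and
#' instrument-style with metadata rows before a `"Sample Name"` header) plus
#' the ground-truth flags.
#'
#' @param run Result of [simulate_run()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_run_fixtures <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  delim <- file.path(dir, "counts.csv")
  instr <- file.path(dir, "counts_instrument.csv")
  truth <- file.path(dir, "truth.csv")
  counts <- run$counts
  colnames(counts)[1L] <- "probe_id"
  readr::write_csv(counts, delim, progress = FALSE)
  meta <- c(sprintf("Instrument,EdgeSeq-sim seed %d", run$config$seed),
            sprintf("Scenario,%s", run$config$scenario),
            sprintf("Samples,%d", run$config$n_samples),
            "")
  header <- paste(c("Sample Name", colnames(counts)[-1L]), collapse = ",")
  num <- counts_tbl_to_matrix(counts)
  body <- vapply(seq_len(nrow(num)),
                 function(i) paste(c(rownames(num)[i],
                                     format(num[i, ], scientific = FALSE, trim = TRUE)),
                                   collapse = ","),
                 character(1L))
  writeLines(c(meta, header, body), instr)
  readr::write_csv(run$truth, truth, progress = FALSE)
  invisible(c(delimited = delim, instrument = instr, truth = truth))
}
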